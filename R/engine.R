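# ---------------------------------------------------------------------------
# The device ring: a simulation is an ordered list of devices executed once
# per time step (one turn = one step).  Each device is gated by a "when"
# global variable, may be restricted to a subgrid (or to "nowhere" = global
# variables only), and reads/writes layers of the 4D state grid or globals.
# Device parameters are literals, expressions over globals, or "@layer"
# bindings resolved per node.
# ---------------------------------------------------------------------------

# ---- expression mini-language --------------------------------------------
# Grammar: reals, + - * / , parentheses, unary minus, variables, and the
# functions eq, ne, gt, ge, lt, le (returning exactly 1.0/0.0), mod(a,b),
# ifle0(c,a,b) (a if c <= 0 else b), abs, min, max.  Unknown identifiers
# are a config error at parse time; mod(a,0) and division by zero are
# runtime errors.

kexpr_functions <- c("eq", "ne", "gt", "ge", "lt", "le", "mod", "ifle0",
                     "abs", "min", "max")

make_kexpr_env <- function() {
  e <- new.env(parent = baseenv())
  e$eq <- function(a, b) as.numeric(a == b)
  e$ne <- function(a, b) as.numeric(a != b)
  e$gt <- function(a, b) as.numeric(a > b)
  e$ge <- function(a, b) as.numeric(a >= b)
  e$lt <- function(a, b) as.numeric(a < b)
  e$le <- function(a, b) as.numeric(a <= b)
  e$mod <- function(a, b) {
    if (any(b == 0)) stop("mod(a, 0)")
    a %% b
  }
  e$ifle0 <- function(c, a, b) ifelse(c <= 0, a, b)
  e$abs <- base::abs
  e$min <- base::pmin
  e$max <- base::pmax
  e$`/` <- function(a, b) {
    if (any(b == 0)) stop("division by zero")
    base::`/`(a, b)
  }
  e$`+` <- base::`+`; e$`-` <- base::`-`; e$`*` <- base::`*`
  e$`(` <- base::`(`
  e
}

tokenize_kexpr <- function(text) {
  pat <- "([0-9]*\\.?[0-9]+([eE][+-]?[0-9]+)?)|([A-Za-z_][A-Za-z0-9_]*)|([-+*/(),])"
  toks <- regmatches(text, gregexpr(pat, text))[[1]]
  # verify nothing but whitespace between tokens
  resid <- text
  regmatches(resid, gregexpr(pat, resid)) <- list(rep("", length(toks)))
  if (grepl("[^[:space:]]", resid)) {
    stop("expression contains unsupported characters: ", text)
  }
  toks
}

#' Parse an expression of the simulation mini-language
#'
#' Supports reals, `+ - * /`, parentheses, unary minus, variables, and the
#' functions `eq ne gt ge lt le` (returning exactly 1.0/0.0), `mod`,
#' `ifle0(c, a, b)`, `abs`, `min`, `max` (elementwise).  Every identifier
#' is checked against `known_vars` at parse time.
#'
#' @param text expression text, e.g. `"eq(mod(t,10),0)"`.
#' @param known_vars character vector of variable names that may appear.
#' @return an object of class `kexpr` (compiled expression).
#' @export
parse_kexpr <- function(text, known_vars = character(0)) {
  toks <- tokenize_kexpr(text)
  ids <- grep("^[A-Za-z_]", toks, value = TRUE)
  is_fun <- logical(length(toks))
  for (i in seq_along(toks)) {
    if (grepl("^[A-Za-z_]", toks[i]) && i < length(toks) && toks[i + 1] == "(") {
      is_fun[i] <- TRUE
      if (!(toks[i] %in% kexpr_functions)) {
        stop("unknown function in expression: ", toks[i])
      }
    }
  }
  vars <- unique(toks[grepl("^[A-Za-z_]", toks) & !is_fun])
  unknown <- setdiff(vars, known_vars)
  if (length(unknown)) {
    stop("unknown identifier(s) in expression: ",
         paste(unknown, collapse = ", "))
  }
  expr <- tryCatch(str2lang(text), error = function(e) {
    stop("malformed expression: ", text)
  })
  structure(list(text = text, expr = expr, vars = vars), class = "kexpr")
}

#' Evaluate a parsed mini-language expression
#'
#' @param kx a `kexpr` from [parse_kexpr()], or expression text (parsed
#'   with the context names as known variables).
#' @param context named list or environment of variable values (vectors
#'   allowed; comparison functions stay elementwise).
#' @return numeric result.
#' @export
eval_expr <- function(kx, context = list()) {
  if (is.character(kx)) {
    nms <- if (is.environment(context)) ls(context) else names(context)
    kx <- parse_kexpr(kx, nms)
  }
  fe <- make_kexpr_env()
  ev <- if (is.environment(context)) {
    # chain: context lookups fall through to the function env
    e <- new.env(parent = fe)
    for (nm in ls(context)) assign(nm, get(nm, envir = context), envir = e)
    e
  } else {
    list2env(as.list(context), parent = fe)
  }
  eval(kx$expr, ev)
}

# a program is an ordered list of assignments "name = expr; name2 = expr2"
parse_kprogram <- function(text, known_vars, target_vars) {
  stmts <- strsplit(text, ";")[[1]]
  stmts <- trimws(stmts)
  stmts <- stmts[stmts != ""]
  out <- vector("list", length(stmts))
  defined <- character(0)
  for (i in seq_along(stmts)) {
    m <- regmatches(stmts[i], regexec("^([A-Za-z_][A-Za-z0-9_]*)\\s*=\\s*(.*)$",
                                      stmts[i]))[[1]]
    if (length(m) != 3) stop("malformed assignment: ", stmts[i])
    tgt <- m[2]
    if (!(tgt %in% target_vars)) {
      stop("assignment target not allowed here: ", tgt)
    }
    out[[i]] <- list(target = tgt,
                     expr = parse_kexpr(m[3], c(known_vars, defined)))
    defined <- union(defined, tgt)
  }
  out
}

# ---- simulation state -----------------------------------------------------

#' Allocate a simulation state grid
#'
#' The state is a 4D array `nx x ny x nz x nv` (the fourth dimension
#' enumerates layers) plus named global variables (always including the
#' integer step counter `t`, starting at 0, and `always = 1`).  When no
#' geometry is given, the outermost node shell is treated as void (the
#' one-node rind implementing no-flux boundaries on a plain box).
#'
#' @param nx,ny,nz grid dimensions (ignored when `geom` is given).
#' @param nv number of layers.
#' @param geom optional `geometry_grid` defining tissue and fibres.
#' @param globals named list of initial global-variable values.
#' @param h space step for the geometry-less case.
#' @return an object of class `sim_state`.
#' @export
sim_state <- function(nx = NULL, ny = 1, nz = 1, nv, geom = NULL,
                      globals = list(), h = 1) {
  if (is.null(geom)) {
    stopifnot(!is.null(nx))
    geom <- make_box(nx, ny, nz, h = h, rind = TRUE)
  }
  glob <- new.env(parent = emptyenv())
  glob$t <- 0
  glob$always <- 1
  for (nm in names(globals)) assign(nm, globals[[nm]], envir = glob)
  structure(list(u = array(0, dim = c(geom$nx, geom$ny, geom$nz, nv)),
                 glob = glob, geom = geom,
                 nx = geom$nx, ny = geom$ny, nz = geom$nz, nv = nv),
            class = "sim_state")
}

#' Read a global variable from a simulation state
#' @param state a `sim_state`.
#' @param name global-variable name.
#' @return its value.
#' @export
get_global <- function(state, name) get(name, envir = state$glob)

state_layer <- function(state, v) state$u[, , , v + 1, drop = TRUE]

space_indices <- function(state, space) {
  if (is.null(space)) {
    list(x = seq_len(state$nx), y = seq_len(state$ny), z = seq_len(state$nz))
  } else {
    list(x = (space$x0:space$x1) + 1, y = (space$y0:space$y1) + 1,
         z = (space$z0:space$z1) + 1)
  }
}

# ---- device constructors --------------------------------------------------

new_device <- function(type, name = type, when = NULL, space = NULL, ...) {
  structure(list(type = type, name = name, when = when, space = space,
                 pars = list(...)),
            class = "sim_device")
}

#' Device constructors for the simulation ring
#'
#' Each constructor returns a device specification to be placed, in order,
#' into the ring executed by [run_ring()].  Common arguments: `when` names
#' a global variable gating execution (`NULL` = always), `space` is a list
#' `(x0, x1, y0, y1, z0, z1)` of 0-based inclusive subgrid bounds (`NULL`
#' = whole grid), `name` labels the instance in logs.
#'
#' @param pgm program text: ordered assignments separated by `;`.
#' @param nowhere logical; `TRUE` restricts a `k_func` to global variables
#'   only (layer writes become a config error).
#' @param when,space,name see above.
#' @return a `sim_device`.
#' @export
#' @rdname devices
dev_k_func <- function(pgm, nowhere = FALSE, when = NULL, space = NULL,
                       name = "k_func") {
  new_device("k_func", name, when, space, pgm = pgm, nowhere = nowhere)
}

#' @param operation one of `"max"`, `"min"`, `"sum"`, `"mean"`.
#' @param v0 source layer (0-based).
#' @param result name of the global receiving the reduction.
#' @export
#' @rdname devices
dev_reduce <- function(operation, v0, result, when = NULL, space = NULL,
                       name = "reduce") {
  stopifnot(operation %in% c("max", "min", "sum", "mean"))
  new_device("reduce", name, when, space, operation = operation, v0 = v0,
             result = result)
}

#' @param expr monitored expression (crossing detector input).
#' @param sign +1 fires on upward zero crossings (previous < 0, current
#'   >= 0), -1 on downward ones.
#' @export
#' @rdname devices
dev_k_poincare <- function(expr, pgm = "", sign = 1, when = NULL,
                           name = "k_poincare") {
  stopifnot(sign %in% c(1, -1))
  new_device("k_poincare", name, when, NULL, expr = expr, pgm = pgm,
             sign = sign)
}

#' @param v1 destination layer (0-based); for `dev_euler` the state occupies
#'   layers `v0..v1`.
#' @param Dpar,Dtrans along-/cross-fibre diffusivities (numbers or
#'   expressions over globals, evaluated at ring-compile time).
#' @param hx space step.
#' @export
#' @rdname devices
dev_diff <- function(v0, v1, Dpar, Dtrans = Dpar, hx, when = NULL,
                     space = NULL, name = "diff") {
  new_device("diff", name, when, space, v0 = v0, v1 = v1, Dpar = Dpar,
             Dtrans = Dtrans, hx = hx)
}

#' @param ht time step.
#' @export
#' @rdname devices
dev_diffstep <- function(v0, v1, Dpar, Dtrans = Dpar, hx, ht, when = NULL,
                         space = NULL, name = "diffstep") {
  new_device("diffstep", name, when, space, v0 = v0, v1 = v1, Dpar = Dpar,
             Dtrans = Dtrans, hx = hx, ht = ht)
}

#' @param ode model registry name (e.g. `"fhncub"`).
#' @param par named list of model parameters: numbers, expression strings
#'   over globals (re-evaluated every turn), or `"@N"` layer bindings
#'   resolved per node.
#' @param solver `"euler"` or `"rk4"`.
#' @export
#' @rdname devices
dev_euler <- function(v0, v1, ht, ode, par = list(), when = NULL,
                      space = NULL, name = "euler", solver = "euler") {
  new_device("ode_solver", name, when, space, v0 = v0, v1 = v1, ht = ht,
             ode = ode, par = par, solver = solver)
}

#' @export
#' @rdname devices
dev_rk4 <- function(v0, v1, ht, ode, par = list(), when = NULL,
                    space = NULL, name = "rk4") {
  dev_euler(v0, v1, ht, ode, par, when, space, name, solver = "rk4")
}

#' @param vmin,vmax,ntab tabulation range and size for the exponential
#'   solver (`NULL` disables tabulation).
#' @export
#' @rdname devices
dev_rushlarsen <- function(v0, v1, ht, ionic, par = list(), vmin = NULL,
                           vmax = NULL, ntab = 20000, when = NULL,
                           space = NULL, name = "rushlarsen") {
  new_device("rushlarsen", name, when, space, v0 = v0, v1 = v1, ht = ht,
             ionic = ionic, par = par, vmin = vmin, vmax = vmax, ntab = ntab)
}

#' @param ionic ionic model name for `dev_rushlarsen`.
#' @param tolerance,upper_level,vcycles,preiter,postiter,maxiter,delta
#'   elliptic solver controls (see [elliptic_problem()]).
#' @param xpin,ypin,zpin,upin pinning condition of the elliptic solution.
#' @export
#' @rdname devices
dev_elliptic <- function(v0, v1, Dpar, Dtrans = Dpar, hx, tolerance = 1e-8,
                         upper_level = 3, vcycles = 20, preiter = 1,
                         postiter = 2, maxiter = 1e6, delta = 0.5,
                         xpin = 0, ypin = 0, zpin = 0, upin = 0,
                         when = NULL, space = NULL, name = "elliptic") {
  new_device("elliptic", name, when, space, v0 = v0, v1 = v1, Dpar = Dpar,
             Dtrans = Dtrans, hx = hx, tolerance = tolerance,
             upper_level = upper_level, vcycles = vcycles, preiter = preiter,
             postiter = postiter, maxiter = maxiter, delta = delta,
             xpin = xpin, ypin = ypin, zpin = zpin, upin = upin)
}

#' @export
#' @rdname devices
dev_stop <- function(when = NULL, name = "stop") {
  new_device("stop", name, when, NULL)
}

#' @param file output path (record/k_print/dump/load/ppmout; ppmout treats
#'   it as a `sprintf` pattern applied to the call ordinal).
#' @export
#' @rdname devices
dev_record <- function(file, v0, v1 = v0, when = NULL, space = NULL,
                       name = "record") {
  new_device("record", name, when, space, file = file, v0 = v0, v1 = v1)
}

#' @param list character vector of global expressions printed per firing.
#' @export
#' @rdname devices
dev_k_print <- function(list, file = "", when = NULL, name = "k_print") {
  new_device("k_print", name, when, NULL, list = list, file = file)
}

#' @export
#' @rdname devices
dev_dump <- function(file, when = NULL, name = "dump") {
  new_device("dump", name, when, NULL, file = file)
}

#' @export
#' @rdname devices
dev_load <- function(file, when = NULL, name = "load") {
  new_device("load", name, when, NULL, file = file)
}

#' @param r,g,b layer indices for the three colour channels (`NULL` = 0).
#' @param r0,r1,g0,g1,b0,b1 value ranges discretised to bytes 0..255.
#' @export
#' @rdname devices
dev_ppmout <- function(file, r = NULL, g = NULL, b = NULL,
                       r0 = 0, r1 = 1, g0 = 0, g1 = 1, b0 = 0, b1 = 1,
                       when = NULL, space = NULL, name = "ppmout") {
  new_device("ppmout", name, when, space, file = file, r = r, g = g, b = b,
             r0 = r0, r1 = r1, g0 = g0, g1 = g1, b0 = b0, b1 = b1)
}

#' @param a,b layer indices of the two fields whose isoline intersections
#'   define phase singularities (`dev_singz`).
#' @param a0,b0 isovalues.
#' @param z z-slice (0-based).
#' @export
#' @rdname devices
dev_singz <- function(a, b, a0, b0, z = 0, file = NULL, when = NULL,
                      name = "singz") {
  new_device("singz", name, when, NULL, a = a, b = b, a0 = a0, b0 = b0,
             z = z, file = file)
}

# ---- ring compilation -----------------------------------------------------

resolve_par <- function(x, glob) {
  if (is.numeric(x)) return(x)
  if (is.character(x)) return(eval_expr(parse_kexpr(x, ls(glob)), glob))
  stop("parameter must be numeric or an expression string")
}

compile_device <- function(dev, state) {
  geom <- state$geom
  glob_names <- ls(state$glob)
  layer_names <- paste0("u", seq_len(state$nv) - 1)
  cache <- new.env(parent = emptyenv())
  p <- dev$pars
  if (dev$type == "k_func") {
    known <- c(glob_names, "t")
    if (!isTRUE(p$nowhere)) {
      known <- c(known, "x", "y", "z", "xmax", "ymax", "zmax", layer_names)
      targets <- layer_names
    } else {
      targets <- c(glob_names, "t")
    }
    cache$prog <- parse_kprogram(p$pgm, known, targets)
    if (isTRUE(p$nowhere)) {
      bad <- vapply(cache$prog, function(a) a$target %in% layer_names,
                    logical(1))
      if (any(bad)) stop("k_func '", dev$name,
                         "': layer write in nowhere mode is a config error")
    }
  } else if (dev$type == "k_poincare") {
    known <- c(glob_names, "t")
    cache$expr <- parse_kexpr(p$expr, known)
    cache$prog <- if (nzchar(p$pgm)) parse_kprogram(p$pgm, known, known) else list()
    cache$prev <- NA_real_
  } else if (dev$type %in% c("diff", "diffstep")) {
    Dpar <- resolve_par(p$Dpar, state$glob)
    Dtrans <- resolve_par(p$Dtrans, state$glob)
    hx <- resolve_par(p$hx, state$glob)
    tensor <- build_tensor(geom, Dpar, Dtrans)
    cache$weights <- build_weights(geom, tensor, hx)
    if (dev$type == "diffstep") cache$ht <- resolve_par(p$ht, state$glob)
  } else if (dev$type == "elliptic") {
    Dpar <- resolve_par(p$Dpar, state$glob)
    Dtrans <- resolve_par(p$Dtrans, state$glob)
    hx <- resolve_par(p$hx, state$glob)
    tensor <- build_tensor(geom, Dpar, Dtrans)
    cache$problem <- elliptic_problem(
      geom, tensor, xpin = p$xpin, ypin = p$ypin, zpin = p$zpin,
      upin = p$upin, tolerance = p$tolerance, upper_level = p$upper_level,
      vcycles = p$vcycles, preiter = p$preiter, postiter = p$postiter,
      maxiter = p$maxiter, delta = p$delta, h = hx)
  } else if (dev$type == "ode_solver") {
    cache$model <- get_model(p$ode)
    cache$ht <- resolve_par(p$ht, state$glob)
    nlay <- p$v1 - p$v0 + 1
    if (nlay != cache$model$n_var) {
      stop("device '", dev$name, "': layers v0..v1 (", nlay,
           ") do not match model state dimension (", cache$model$n_var, ")")
    }
  } else if (dev$type == "rushlarsen") {
    cache$model <- get_model(p$ionic)
    cache$ht <- resolve_par(p$ht, state$glob)
    cache$tables <- NULL
    if (!is.null(p$vmin) && !is.null(p$vmax)) {
      cache$tables <- ionic_tables(cache$model, cache$ht, p$vmin, p$vmax,
                                   p$ntab)
    }
  } else if (dev$type == "record") {
    cache$count <- 0L
    if (file.exists(p$file)) unlink(p$file)
  } else if (dev$type == "k_print") {
    known <- c(glob_names, "t")
    cache$exprs <- lapply(p$list, parse_kexpr, known_vars = known)
    if (nzchar(p$file) && file.exists(p$file)) unlink(p$file)
  } else if (dev$type == "ppmout") {
    cache$ordinal <- 0L
  }
  cache
}

eval_device_pars <- function(par, state, sub) {
  # literal / expression-over-globals / "@layer" binding
  out <- list()
  for (nm in names(par)) {
    v <- par[[nm]]
    if (is.character(v) && grepl("^@", v)) {
      lay <- as.integer(sub("^@", "", v)) + 1
      out[[nm]] <- as.vector(state$u[sub$x, sub$y, sub$z, lay])
    } else if (is.character(v)) {
      out[[nm]] <- eval_expr(parse_kexpr(v, ls(state$glob)), state$glob)
    } else {
      out[[nm]] <- v
    }
  }
  out
}

format_fixed <- function(x) sprintf("%+.7e", x)

run_device <- function(dev, cache, state, echo = FALSE) {
  p <- dev$pars
  glob <- state$glob
  sub <- space_indices(state, dev$space)
  tis <- state$geom$status[sub$x, sub$y, sub$z, drop = FALSE] != 0

  if (dev$type == "k_func") {
    if (isTRUE(p$nowhere)) {
      for (a in cache$prog) {
        assign(a$target, eval_expr(a$expr, glob), envir = glob)
      }
    } else {
      nxs <- length(sub$x); nys <- length(sub$y); nzs <- length(sub$z)
      ctx <- new.env(parent = emptyenv())
      for (nm in ls(glob)) assign(nm, get(nm, envir = glob), envir = ctx)
      ctx$x <- array(rep(sub$x - 1, times = nys * nzs), dim = c(nxs, nys, nzs))
      ctx$y <- array(rep(rep(sub$y - 1, each = nxs), times = nzs),
                     dim = c(nxs, nys, nzs))
      ctx$z <- array(rep(sub$z - 1, each = nxs * nys), dim = c(nxs, nys, nzs))
      ctx$xmax <- state$nx; ctx$ymax <- state$ny; ctx$zmax <- state$nz
      for (v in seq_len(state$nv)) {
        assign(paste0("u", v - 1),
               array(state$u[sub$x, sub$y, sub$z, v], dim = dim(tis)),
               envir = ctx)
      }
      for (a in cache$prog) {
        val <- eval_expr(a$expr, ctx)
        lay <- as.integer(sub("^u", "", a$target)) + 1
        cur <- array(state$u[sub$x, sub$y, sub$z, lay], dim = dim(tis))
        val <- array(val, dim = dim(tis))
        cur[tis] <- val[tis]
        state$u[sub$x, sub$y, sub$z, lay] <- cur
        assign(a$target, cur, envir = ctx)
      }
    }
  } else if (dev$type == "reduce") {
    vals <- state$u[sub$x, sub$y, sub$z, p$v0 + 1, drop = FALSE][tis]
    if (!length(vals)) stop("reduce '", dev$name,
                            "': space restriction contains no tissue")
    r <- switch(p$operation, max = max(vals), min = min(vals),
                sum = sum(vals), mean = mean(vals))
    assign(p$result, r, envir = glob)
  } else if (dev$type == "k_poincare") {
    cur <- eval_expr(cache$expr, glob)
    prev <- cache$prev
    fired <- FALSE
    if (!is.na(prev)) {
      if (p$sign > 0) fired <- prev < 0 && cur >= 0
      else fired <- prev > 0 && cur <= 0
    }
    if (fired) {
      for (a in cache$prog) {
        assign(a$target, eval_expr(a$expr, glob), envir = glob)
      }
    }
    cache$prev <- cur
  } else if (dev$type == "diff") {
    u <- state$u[, , , p$v0 + 1, drop = TRUE]
    L <- apply_diffusion(u, cache$weights)
    full <- array(state$u[, , , p$v1 + 1], dim = dim(cache$weights$psi))
    msk <- cache$weights$psi != 0
    full[msk] <- L[msk]
    state$u[, , , p$v1 + 1] <- full
  } else if (dev$type == "diffstep") {
    u <- array(state$u[, , , p$v0 + 1], dim = dim(cache$weights$psi))
    L <- apply_diffusion(u, cache$weights)
    state$u[, , , p$v1 + 1] <- L
    state$u[, , , p$v0 + 1] <- u + cache$ht * L
  } else if (dev$type == "elliptic") {
    S <- state$u[, , , p$v0 + 1, drop = TRUE]
    init <- as.vector(state$u[, , , p$v1 + 1])
    sol <- solve_elliptic(cache$problem, rhs = S, init = init)
    state$u[, , , p$v1 + 1] <- sol$phi
  } else if (dev$type == "ode_solver") {
    state <- run_ode_device(dev, cache, state, sub, tis)
  } else if (dev$type == "rushlarsen") {
    lay <- (p$v0:p$v1) + 1
    lin <- which(tis)
    arr <- which(tis, arr.ind = TRUE)
    pars <- eval_device_pars(p$par, state, sub)
    for (r in seq_len(nrow(arr))) {
      i <- sub$x[arr[r, 1]]; j <- sub$y[arr[r, 2]]; l <- sub$z[arr[r, 3]]
      st <- state$u[i, j, l, lay]
      pr <- lapply(pars, function(v) if (length(v) > 1) v[lin[r]] else v)
      state$u[i, j, l, lay] <- ionic_step(st, cache$model, pr, cache$ht,
                                          cache$tables)
    }
  } else if (dev$type == "stop") {
    state$terminated <- TRUE
  } else if (dev$type == "record") {
    lay <- (p$v0:p$v1) + 1
    vals <- as.vector(state$u[sub$x, sub$y, sub$z, lay])
    cat(paste(format_fixed(vals), collapse = " "), "\n",
        file = p$file, append = TRUE, sep = "")
    cache$count <- cache$count + 1L
  } else if (dev$type == "k_print") {
    vals <- vapply(cache$exprs, eval_expr, numeric(1), context = glob)
    line <- paste(format_fixed(vals), collapse = " ")
    if (nzchar(p$file)) cat(line, "\n", file = p$file, append = TRUE, sep = "")
    else cat(line, "\n", sep = "")
  } else if (dev$type == "dump") {
    con <- file(p$file, "wb")
    writeBin(as.vector(state$u), con, size = 8, endian = "little")
    close(con)
  } else if (dev$type == "load") {
    con <- file(p$file, "rb")
    vals <- readBin(con, "double", n = length(state$u), size = 8,
                    endian = "little")
    close(con)
    if (length(vals) != length(state$u)) {
      stop("load '", dev$name, "': file size does not match the state grid")
    }
    state$u <- array(vals, dim = dim(state$u))
  } else if (dev$type == "ppmout") {
    fname <- sprintf(p$file, cache$ordinal)
    layers <- lapply(list(p$r, p$g, p$b), function(v)
      if (is.null(v)) NULL else state$u[sub$x, sub$y, sub$z, v + 1, drop = FALSE])
    ppm_write(layers[[1]], layers[[2]], layers[[3]],
              c(p$r0, p$r1, p$g0, p$g1, p$b0, p$b1), fname)
    cache$ordinal <- cache$ordinal + 1L
  } else if (dev$type == "singz") {
    a <- state$u[, , p$z + 1, p$a + 1]
    b <- state$u[, , p$z + 1, p$b + 1]
    tips <- singz_find(a, b, p$a0, p$b0,
                       tissue = state$geom$status[, , p$z + 1] != 0)
    glob$singz_n <- tips$stats$n
    if (tips$stats$n > 0) {
      glob$singz_x <- tips$stats$mean_x
      glob$singz_y <- tips$stats$mean_y
    }
    if (!is.null(p$file)) {
      utils::write.table(tips$tips, p$file, row.names = FALSE,
                         col.names = FALSE, append = TRUE)
    }
  } else {
    stop("unknown device type: ", dev$type)
  }
  state
}

run_ode_device <- function(dev, cache, state, sub, tis) {
  p <- dev$pars
  model <- cache$model
  lay <- (p$v0:p$v1) + 1
  pars <- eval_device_pars(p$par, state, sub)
  k <- cache$ht
  nt <- sum(tis)
  if (!nt) return(state)
  # vectorized path when the model provides it and solver is euler
  if (!is.null(model$rhs_vec) && identical(p$solver, "euler")) {
    U <- matrix(0, nt, length(lay))
    for (c in seq_along(lay)) {
      U[, c] <- state$u[sub$x, sub$y, sub$z, lay[c], drop = FALSE][tis]
    }
    prm <- merge_params(model$defaults, lapply(pars, function(v)
      if (length(v) > 1) v[as.vector(tis)] else v))
    dU <- model$rhs_vec(U, prm)
    U <- U + k * dU
    for (c in seq_along(lay)) {
      full <- state$u[sub$x, sub$y, sub$z, lay[c], drop = FALSE]
      full[tis] <- U[, c]
      state$u[sub$x, sub$y, sub$z, lay[c]] <- full
    }
    return(state)
  }
  stepper <- get_solver(p$solver)
  idx <- which(tis)
  arr <- which(tis, arr.ind = TRUE)
  for (r in seq_len(nrow(arr))) {
    i <- sub$x[arr[r, 1]]; j <- sub$y[arr[r, 2]]; l <- sub$z[arr[r, 3]]
    st <- state$u[i, j, l, lay]
    pr <- lapply(pars, function(v) if (length(v) > 1) v[idx[r]] else v)
    state$u[i, j, l, lay] <- stepper(st, model, pr, k)
  }
  state
}

#' Run a device ring
#'
#' Executes the devices once per turn in declaration order; a device runs on
#' a turn iff its `when` global is nonzero.  A `stop` device terminates the
#' run immediately at its ring position; the step counter `t` increments
#' after the last device of each completed turn.  The parsed ring is echoed
#' to the run log when `echo = TRUE`.
#'
#' @param ring list of `sim_device` objects (declaration order = execution
#'   order).
#' @param state a `sim_state`.
#' @param max_turns safety cap when the ring carries no `stop` device.
#' @param echo print the parsed ring before running.
#' @return the final `sim_state`, with attribute `turns` (completed turns)
#'   and `device_stats` (per-device firing counts).
#' @export
run_ring <- function(ring, state, max_turns = 1e6, echo = FALSE) {
  stopifnot(all(vapply(ring, inherits, logical(1), "sim_device")))
  has_stop <- any(vapply(ring, function(d) d$type == "stop", logical(1)))
  if (!has_stop && !is.finite(max_turns)) {
    stop("ring has no stop device and no finite max_turns")
  }
  caches <- lapply(ring, compile_device, state = state)
  fired <- integer(length(ring))
  if (echo) {
    for (i in seq_along(ring)) {
      d <- ring[[i]]
      message(sprintf("ring[%d]: %s '%s' when=%s", i, d$type, d$name,
                      if (is.null(d$when)) "always" else d$when))
    }
  }
  state$terminated <- FALSE
  turns <- 0L
  while (turns < max_turns) {
    for (i in seq_along(ring)) {
      d <- ring[[i]]
      flag <- if (is.null(d$when)) 1 else get(d$when, envir = state$glob)
      if (flag != 0) {
        state <- tryCatch(run_device(d, caches[[i]], state),
                          error = function(e) {
          stop(sprintf("device '%s' (type %s) failed at t = %d: %s",
                       d$name, d$type, as.integer(state$glob$t),
                       conditionMessage(e)), call. = FALSE)
        })
        fired[i] <- fired[i] + 1L
        if (isTRUE(state$terminated)) break
      }
    }
    if (isTRUE(state$terminated)) break
    state$glob$t <- state$glob$t + 1
    turns <- turns + 1L
  }
  attr(state, "turns") <- turns
  attr(state, "device_stats") <- data.frame(
    name = vapply(ring, `[[`, character(1), "name"),
    type = vapply(ring, `[[`, character(1), "type"),
    fired = fired)
  state
}

# ---- standalone operations used by devices --------------------------------

#' Feedback stimulation force
#'
#' The delay-line feedback formula: a stimulus of amplitude `Amp` (scaled by
#' the time step `ht`) active from `Del` after the last registered front
#' arrival time `Tfront` for a duration `Dur`, once the protocol is enabled
#' (`T >= Tstart`): `force = ht*Amp*ge(T,Tstart)*ge(T,Tfront+Del)*le(T,Tfront+Del+Dur)`.
#'
#' @param T current model time.
#' @param Tfront last front-arrival time latched by the crossing detector.
#' @param Tstart protocol enable time.
#' @param Del delay between front registration and stimulus onset.
#' @param Dur stimulus duration.
#' @param Amp stimulus amplitude.
#' @param ht time step.
#' @return the force value (0 outside the stimulation window).
#' @export
feedback_force <- function(T, Tfront, Tstart, Del, Dur, Amp, ht) {
  ht * Amp * (T >= Tstart) * (T >= Tfront + Del) * (T <= Tfront + Del + Dur)
}

#' Locate phase singularities in a 2D slice
#'
#' Intersects, within every 2x2 cell of tissue nodes, the linearly
#' interpolated isoline segments `a = a0` and `b = b0`; intersection points
#' falling inside the cell are spiral-wave tips (phase singularities).
#' Exact for linear fields.
#'
#' @param a,b numeric matrices (two field layers on the slice).
#' @param a0,b0 isovalues.
#' @param tissue optional logical matrix; cells with any non-tissue corner
#'   are skipped.
#' @return list with `tips` (data.frame of fractional 0-based grid
#'   coordinates `x`, `y`) and `stats` (`n`, means and standard deviations
#'   of the coordinates; `NA` when no tips are found, flagged by `n = 0`).
#' @export
singz_find <- function(a, b, a0 = 0, b0 = 0, tissue = NULL) {
  A <- a - a0
  B <- b - b0
  nx <- nrow(A); ny <- ncol(A)
  xs <- numeric(0); ys <- numeric(0)
  segs <- function(F, i, j) {
    # crossing points of F = 0 on the edges of cell (i, j)..(i+1, j+1),
    # in cell-local coordinates [0,1]^2
    corners <- c(F[i, j], F[i + 1, j], F[i + 1, j + 1], F[i, j + 1])
    edges <- list(c(1, 2), c(2, 3), c(3, 4), c(4, 1))
    exy <- list(c(0, 0, 1, 0), c(1, 0, 1, 1), c(1, 1, 0, 1), c(0, 1, 0, 0))
    pts <- NULL
    for (e in seq_len(4)) {
      f1 <- corners[edges[[e]][1]]; f2 <- corners[edges[[e]][2]]
      if ((f1 < 0 && f2 >= 0) || (f1 >= 0 && f2 < 0)) {
        s <- f1 / (f1 - f2)
        co <- exy[[e]]
        pts <- rbind(pts, c(co[1] + s * (co[3] - co[1]),
                            co[2] + s * (co[4] - co[2])))
      }
    }
    pts
  }
  seg_intersect <- function(p1, p2, q1, q2) {
    d1 <- p2 - p1; d2 <- q2 - q1
    den <- d1[1] * d2[2] - d1[2] * d2[1]
    if (abs(den) < 1e-14) return(NULL)
    rhs <- q1 - p1
    tpar <- (rhs[1] * d2[2] - rhs[2] * d2[1]) / den
    spar <- (rhs[1] * d1[2] - rhs[2] * d1[1]) / den
    if (tpar < -1e-12 || tpar > 1 + 1e-12 ||
        spar < -1e-12 || spar > 1 + 1e-12) return(NULL)
    p1 + tpar * d1
  }
  for (i in seq_len(nx - 1)) {
    for (j in seq_len(ny - 1)) {
      if (!is.null(tissue)) {
        if (!(tissue[i, j] && tissue[i + 1, j] && tissue[i, j + 1] &&
              tissue[i + 1, j + 1])) next
      }
      pa <- segs(A, i, j)
      if (is.null(pa) || nrow(pa) < 2) next
      pb <- segs(B, i, j)
      if (is.null(pb) || nrow(pb) < 2) next
      # pair crossings into segments (2 crossings: one segment; 4: two,
      # paired by traversal order)
      pair <- function(pts) {
        if (nrow(pts) == 2) list(pts) else
          list(pts[1:2, , drop = FALSE], pts[3:4, , drop = FALSE])
      }
      for (sa in pair(pa)) for (sb in pair(pb)) {
        hit <- seg_intersect(sa[1, ], sa[2, ], sb[1, ], sb[2, ])
        if (!is.null(hit)) {
          xs <- c(xs, (i - 1) + hit[1])
          ys <- c(ys, (j - 1) + hit[2])
        }
      }
    }
  }
  n <- length(xs)
  stats <- list(n = n,
                mean_x = if (n) mean(xs) else NA_real_,
                mean_y = if (n) mean(ys) else NA_real_,
                sd_x = if (n > 1) stats::sd(xs) else NA_real_,
                sd_y = if (n > 1) stats::sd(ys) else NA_real_)
  list(tips = data.frame(x = xs, y = ys), stats = stats)
}

#' Write a stacked-slice binary PPM (P6) image of up to three layers
#'
#' Each value is discretised to one byte:
#' `clamp(round(255*(v - v0)/(v1 - v0)), 0, 255)` with round-half-up.  The
#' file is binary P6, width `nx`, height `ny*nz` (z-slices stacked), maxval
#' 255, pixels ordered x-fastest, then y, then z.  Missing channels write 0.
#'
#' @param r,g,b numeric arrays (same spatial dims) or `NULL`.
#' @param ranges numeric length-6 `(r0, r1, g0, g1, b0, b1)`; a degenerate
#'   range on a used channel is a config error.
#' @param path output file.
#' @return the path, invisibly.
#' @export
ppm_write <- function(r, g, b, ranges, path) {
  chans <- list(r, g, b)
  dims <- NULL
  for (ch in chans) if (!is.null(ch)) dims <- dim(array(ch, dim = dim(ch)))
  if (is.null(dims)) stop("ppm_write: at least one channel required")
  if (length(dims) < 3) dims <- c(dims, rep(1L, 3 - length(dims)))
  n <- prod(dims)
  bytes <- matrix(0L, nrow = 3, ncol = n)
  for (c in 1:3) {
    ch <- chans[[c]]
    v0 <- ranges[2 * c - 1]; v1 <- ranges[2 * c]
    if (!is.null(ch)) {
      if (v1 == v0) stop("ppm_write: degenerate range on channel ", c)
      sc <- 255 * (as.vector(ch) - v0) / (v1 - v0)
      bytes[c, ] <- pmin(pmax(as.integer(floor(sc + 0.5)), 0L), 255L)
    }
  }
  con <- file(path, "wb")
  on.exit(close(con))
  writeChar(sprintf("P6\n%d %d\n255\n", dims[1], dims[2] * dims[3]), con,
            eos = NULL)
  writeBin(as.raw(as.vector(bytes)), con)
  invisible(path)
}

#' Phase-distribution initial conditions
#'
#' Maps a one-period recording of a wave (a table of `n` rows by `nv`
#' state values) onto a prescribed per-node phase field: each node receives
#' the table evaluated at `phase * n` with linear interpolation between
#' rows and periodic wrap-around.  Used to position re-entrant waves
#' precisely.
#'
#' @param table numeric matrix (`n x nv`): one period of the state cycle.
#' @param phase_map numeric array of phases in `[0, 1)` per node.
#' @param state a `sim_state` whose first `nv` layers receive the values.
#' @param layers 0-based layer indices to fill (default `0:(nv-1)`).
#' @return the updated `sim_state`.
#' @export
phase_distribution_ic <- function(table, phase_map, state,
                                  layers = seq_len(ncol(table)) - 1) {
  table <- as.matrix(table)
  if (nrow(table) < 1) stop("phase table is empty")
  if (length(layers) != ncol(table)) {
    stop("table row length does not match the target layer count")
  }
  if (any(!is.finite(phase_map))) stop("phases must be finite")
  n <- nrow(table)
  ph <- as.vector(phase_map) %% 1
  pos <- ph * n
  i0 <- floor(pos)
  frac <- pos - i0
  i0 <- (i0 %% n) + 1
  i1 <- (i0 %% n) + 1
  for (c in seq_along(layers)) {
    vals <- (1 - frac) * table[i0, c] + frac * table[i1, c]
    state$u[, , , layers[c] + 1] <- array(vals, dim = dim(state$u)[1:3])
  }
  state
}
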