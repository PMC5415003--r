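# ---------------------------------------------------------------------------
# Declarative simulation configs: a structured-text (YAML) file declaring the
# state grid (dimensions or geometry file), global variables, string macros
# and the ordered device ring.  Macros "[name]" are substituted literally in
# device parameter strings before parsing, mirroring the string-macro usage
# of the scripting interface ("def str u 0; ... v0 = [u]").
# ---------------------------------------------------------------------------

expand_macros <- function(x, macros) {
  if (is.character(x) && length(macros)) {
    for (nm in names(macros)) {
      x <- gsub(paste0("[", nm, "]"), as.character(macros[[nm]]), x,
                fixed = TRUE)
    }
    # numeric-looking strings become numbers after substitution
    num <- suppressWarnings(as.numeric(x))
    if (!is.na(num) && grepl("^[-+0-9.eE]+$", trimws(x))) return(num)
  }
  x
}

device_from_config <- function(spec, macros) {
  type <- spec$device
  if (is.null(type)) stop("config device entry lacks a 'device' field")
  spec$device <- NULL
  spec <- lapply(spec, function(v) {
    if (is.list(v)) lapply(v, expand_macros, macros = macros)
    else expand_macros(v, macros)
  })
  ctor <- switch(type,
                 k_func = dev_k_func, reduce = dev_reduce,
                 k_poincare = dev_k_poincare, diff = dev_diff,
                 diffstep = dev_diffstep, euler = dev_euler, rk4 = dev_rk4,
                 rushlarsen = dev_rushlarsen, elliptic = dev_elliptic,
                 stop = dev_stop, record = dev_record, k_print = dev_k_print,
                 dump = dev_dump, load = dev_load, ppmout = dev_ppmout,
                 singz = dev_singz,
                 stop("unknown device type in config: ", type))
  do.call(ctor, spec)
}

#' Read a simulation configuration file
#'
#' Parses a YAML config with sections `state` (either `nx`/`ny`/`nz` for a
#' plain box with a one-node void rind, or `geometry` naming a `.bbg`
#' file, plus `nv` and `h`), optional `globals` (initial values; may be
#' overridden from the command line), optional `macros` (literal `[name]`
#' text substitutions in device parameters), and `devices` (the ordered
#' ring; each entry has a `device` type plus its parameters).
#'
#' @param path config file path.
#' @param params named overrides for `globals` (command-line `name=value`).
#' @return list with `state` (a fresh [sim_state()]) and `ring` (list of
#'   devices for [run_ring()]).
#' @export
read_sim_config <- function(path, params = list()) {
  cfg <- yaml::read_yaml(path)
  if (is.null(cfg$state)) stop("config lacks a 'state' section")
  st <- cfg$state
  globals <- if (is.null(cfg$globals)) list() else cfg$globals
  for (nm in names(params)) globals[[nm]] <- as.numeric(params[[nm]])
  geom <- NULL
  if (!is.null(st$geometry)) {
    gpath <- st$geometry
    if (!file.exists(gpath)) {
      gpath <- file.path(dirname(path), st$geometry)
    }
    dim <- if (!is.null(st$nx)) c(st$nx, st$ny, st$nz) else NULL
    geom <- read_bbg(gpath, dim = dim, h = if (is.null(st$h)) 1 else st$h)
  }
  state <- sim_state(nx = st$nx, ny = if (is.null(st$ny)) 1 else st$ny,
                     nz = if (is.null(st$nz)) 1 else st$nz,
                     nv = st$nv, geom = geom, globals = globals,
                     h = if (is.null(st$h)) 1 else st$h)
  macros <- if (is.null(cfg$macros)) list() else cfg$macros
  ring <- lapply(cfg$devices, device_from_config, macros = macros)
  list(state = state, ring = ring)
}

#' Run a simulation from a config file
#'
#' @param path config file path (see [read_sim_config()]).
#' @param params named global overrides.
#' @param max_turns safety cap on ring turns.
#' @param echo echo the parsed ring.
#' @return the final `sim_state`.
#' @export
run_sim <- function(path, params = list(), max_turns = 1e6, echo = TRUE) {
  cfg <- read_sim_config(path, params)
  run_ring(cfg$ring, cfg$state, max_turns = max_turns, echo = echo)
}
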