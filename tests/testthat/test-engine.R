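test_that("the expression mini-language evaluates the script idioms", {
  expect_identical(eval_expr("eq(mod(20,10),0)"), 1)
  expect_identical(eval_expr("ifle0(25-25, 1.7, -1.7)"), 1.7)
  expect_identical(eval_expr("ifle0(26-25, 1.7, -1.7)"), -1.7)
  expect_identical(eval_expr("ge(3,4)"), 0)
  expect_identical(eval_expr("le(T, Tfront+Del+Dur)",
                             list(T = 5, Tfront = 1, Del = 2, Dur = 2)), 1)
  expect_identical(eval_expr("gt(y,50)", list(y = 51)), 1)
  expect_equal(eval_expr("-x + 2*(3 - 1)/4", list(x = 1)), 0)
  expect_equal(eval_expr("min(3, max(1, 2))"), 2)
  expect_equal(eval_expr("abs(0-2.5)"), 2.5)
  # comparison results are exactly 0.0 / 1.0
  expect_true(eval_expr("lt(1,2)") %in% c(0, 1))
  expect_error(parse_kexpr("nosuch + 1", "x"), "unknown identifier")
  expect_error(parse_kexpr("sin(1)", character(0)), "unknown function")
  expect_error(eval_expr("mod(3, 0)"), "mod")
  expect_error(eval_expr("1/0"), "division by zero")
})

test_that("a minimalist spiral-protocol ring produces exactly 101 records", {
  rec <- withr::local_tempfile(fileext = ".dat")
  st <- sim_state(nx = 22, ny = 22, nv = 3,
                  globals = list(begin = 0, out = 0, end = 0))
  ring <- list(
    dev_k_func("begin = eq(t,0); out = eq(mod(t,10),0); end = ge(t,1000)",
               nowhere = TRUE, name = "timing"),
    dev_k_func("u0 = gt(y,10); u1 = 0.4*lt(x,10)", when = "begin",
               name = "IC"),
    dev_record(rec, v0 = 0, v1 = 1, when = "out",
               space = list(x0 = 10, x1 = 10, y0 = 5, y1 = 5, z0 = 0, z1 = 0)),
    dev_stop(when = "end"),
    dev_diffstep(v0 = 0, v1 = 2, Dpar = 1, hx = 0.4, ht = 0.02),
    dev_euler(v0 = 0, v1 = 1, ht = 0.02, ode = "fhnbkl",
              par = list(a = 0.8, b = 0.01, eps = 0.02)))
  out <- run_ring(ring, st)
  lines <- readLines(rec)
  expect_length(lines, 101)              # t = 0, 10, ..., 1000
  expect_length(strsplit(lines[1], " +")[[1]], 2)   # two values per line
  expect_match(lines[1], "^[+-]\\d\\.\\d{7}e[+-]\\d+")
  stats <- attr(out, "device_stats")
  expect_equal(stats$fired[stats$name == "IC"], 1)  # fires exactly once
  expect_equal(attr(out, "turns"), 1000)
})

test_that("cross-field initial conditions are exact and rind stays void", {
  st <- sim_state(nx = 12, ny = 12, nv = 2, globals = list(begin = 1))
  ring <- list(
    dev_k_func("u0 = gt(y,5); u1 = 0.4*lt(x,5)", when = "begin", name = "IC"),
    dev_stop())
  out <- run_ring(ring, st)
  tis <- out$geom$status[, , 1] != 0
  y <- matrix(rep(0:11, each = 12), 12, 12)
  x <- matrix(rep(0:11, times = 12), 12, 12)
  expect_equal(out$u[, , 1, 1][tis], as.numeric(y > 5)[tis])
  expect_equal(out$u[, , 1, 2][tis], (0.4 * (x < 5))[tis])
  expect_true(all(out$u[1, , 1, 1] == 0))           # rind untouched
})

test_that("k_func supports parameter ramps and nowhere-mode guards", {
  st <- sim_state(nx = 5, ny = 5, nz = 6, nv = 1,
                  globals = list(bet = 0.71, grad = 0.1))
  ring <- list(
    dev_k_func("u0 = bet + grad*(z - 0.5*zmax)", name = "ramp"),
    dev_stop())
  out <- run_ring(ring, st)
  tis <- out$geom$status != 0
  for (zz in 2:5) {
    expect_equal(unique(out$u[, , zz, 1][tis[, , zz]]),
                 0.71 + 0.1 * ((zz - 1) - 3))
  }
  # layer writes in nowhere mode are a config error
  expect_error(run_ring(list(dev_k_func("u0 = 1", nowhere = TRUE),
                             dev_stop()), st),
               "not allowed")
  # empty programs leave the state unchanged
  out2 <- run_ring(list(dev_k_func("", name = "noop"), dev_stop()), st)
  expect_identical(out2$u, st$u)
})

test_that("reduce computes subgrid statistics over tissue", {
  st <- sim_state(nx = 6, ny = 6, nv = 1, globals = list(m = 0))
  st$u[, , 1, 1] <- 7.5
  expect_m <- function(ring_dev, val) {
    out <- run_ring(list(ring_dev, dev_stop()), st)
    expect_equal(get_global(out, "m"), val)
  }
  expect_m(dev_reduce("max", 0, "m"), 7.5)
  st$u[, , 1, 1] <- matrix(rep(0:5, times = 6), 6, 6)  # value = x index
  expect_m(dev_reduce("max", 0, "m"), 4)   # rind excludes x = 5
  st$u[2:3, 2:3, 1, 1] <- matrix(c(1, 2, 3, 4), 2, 2)
  out <- run_ring(list(
    dev_reduce("sum", 0, "m",
               space = list(x0 = 1, x1 = 2, y0 = 1, y1 = 2, z0 = 0, z1 = 0)),
    dev_stop()), st)
  expect_equal(get_global(out, "m"), 10)
  expect_error(run_ring(list(
    dev_reduce("max", 0, "m",
               space = list(x0 = 0, x1 = 0, y0 = 0, y1 = 0, z0 = 0, z1 = 0)),
    dev_stop()), st), "no tissue")
})

test_that("the Poincare detector fires on upward crossings only", {
  # sig = t - 2.5 crosses zero upward between t = 2 and t = 3
  st <- sim_state(nx = 4, ny = 1, nv = 1,
                  globals = list(sig = -1, Tev = -1, end = 0))
  ring <- list(
    dev_k_func("sig = t - 2.5; end = ge(t,6)", nowhere = TRUE),
    dev_k_poincare("sig", pgm = "Tev = t", sign = 1),
    dev_stop(when = "end"))
  out <- run_ring(ring, st)
  expect_equal(get_global(out, "Tev"), 3)

  # monotonically decreasing signal: no event
  st2 <- sim_state(nx = 4, ny = 1, nv = 1,
                   globals = list(sig = 1, Tev = -1, end = 0))
  ring2 <- list(
    dev_k_func("sig = 0 - t; end = ge(t,6)", nowhere = TRUE),
    dev_k_poincare("sig", pgm = "Tev = t", sign = 1),
    dev_stop(when = "end"))
  expect_equal(get_global(run_ring(ring2, st2), "Tev"), -1)

  # periodic sawtooth: exactly one upward event per period over 3 periods
  st3 <- sim_state(nx = 4, ny = 1, nv = 1,
                   globals = list(sig = -1, nev = 0, end = 0))
  ring3 <- list(
    dev_k_func("sig = mod(t,10) - 4.5; end = ge(t,29)", nowhere = TRUE),
    dev_k_poincare("sig", pgm = "nev = nev + 1", sign = 1),
    dev_stop(when = "end"))
  expect_equal(get_global(run_ring(ring3, st3), "nev"), 3)
})

test_that("feedback force obeys the delay-line window", {
  expect_equal(feedback_force(T = 50, Tfront = 48, Tstart = 100, Del = 6,
                              Dur = 0.1, Amp = 3, ht = 0.05), 0)
  expect_equal(feedback_force(T = 106, Tfront = 100, Tstart = 100, Del = 6,
                              Dur = 0.1, Amp = 3, ht = 0.05), 0.15)
  expect_equal(feedback_force(T = 106.11, Tfront = 100, Tstart = 100, Del = 6,
                              Dur = 0.1, Amp = 3, ht = 0.05), 0)
  expect_equal(feedback_force(T = 106.1, Tfront = 100, Tstart = 100, Del = 6,
                              Dur = 0.1, Amp = 3, ht = 0.05), 0.15)
})

test_that("phase-singularity detection is exact on linear fields", {
  nx <- 12; ny <- 10
  x <- matrix(rep(0:(nx - 1), times = ny), nx, ny)
  y <- matrix(rep(0:(ny - 1), each = nx), nx, ny)
  tips <- singz_find(x - 5.3, y - 2.7, 0, 0)
  expect_equal(nrow(tips$tips), 1)
  expect_equal(tips$tips$x, 5.3)
  expect_equal(tips$tips$y, 2.7)
  expect_equal(tips$stats$n, 1)

  # rotated independent linear fields: tip at the 2x2 system root
  a <- 2 * x - y - 7.9          # zero line: y = 2x - 7.9
  b <- x + 3 * y - 20.6         # zero line: x = 20.6 - 3y
  xs <- solve(matrix(c(2, 1, -1, 3), 2, 2, byrow = FALSE), c(7.9, 20.6))
  xs <- solve(matrix(c(2, -1, 1, 3), 2, 2, byrow = TRUE), c(7.9, 20.6))
  tips2 <- singz_find(a, b, 0, 0)
  expect_equal(nrow(tips2$tips), 1)
  expect_equal(c(tips2$tips$x, tips2$tips$y), xs, tolerance = 1e-12)

  # no isoline at all: empty result flagged by n = 0
  tips3 <- singz_find(matrix(1, nx, ny), y - 2.7, 0, 0)
  expect_equal(tips3$stats$n, 0)
  expect_true(is.na(tips3$stats$mean_x))
})

test_that("ppm output discretises bytes and stacks slices", {
  f <- withr::local_tempfile(fileext = ".ppm")
  v <- array(c(0, 0.5, 1), dim = c(3, 1, 1))
  ppm_write(v, NULL, NULL, c(0, 1, 0, 1, 0, 1), f)
  raw <- readBin(f, "raw", n = file.size(f))
  txt <- rawToChar(raw[1:9])
  expect_equal(txt, "P6\n3 1\n25")
  payload <- raw[(length(raw) - 8):length(raw)]
  expect_equal(as.integer(payload[c(1, 4, 7)]), c(0, 128, 255))

  f2 <- withr::local_tempfile(fileext = ".ppm")
  v2 <- array(runif(12), dim = c(3, 2, 2))
  ppm_write(v2, v2, v2, c(0, 1, 0, 1, 0, 1), f2)
  con <- file(f2, "rb")
  hdr <- readLines(con, n = 2)
  expect_equal(hdr[2], "3 4")                  # height = ny * nz
  close(con)
  expect_equal(file.size(f2), nchar("P6\n3 4\n255\n") + 36)

  expect_error(ppm_write(v, NULL, NULL, c(1, 1, 0, 1, 0, 1), f), "degenerate")
})

test_that("dump and load round-trip the state bit-exactly", {
  f <- withr::local_tempfile(fileext = ".bin")
  st <- sim_state(nx = 5, ny = 4, nz = 2, nv = 3)
  set.seed(19)
  st$u[] <- rnorm(length(st$u))
  orig <- st$u
  out <- run_ring(list(dev_dump(f), dev_stop()), st)
  # byte order: x fastest, then y, z, layer slowest, 8-byte little-endian
  vals <- readBin(f, "double", n = length(orig), size = 8, endian = "little")
  expect_identical(vals[1:5], as.vector(orig[, 1, 1, 1]))
  st$u[] <- 0
  out2 <- run_ring(list(dev_load(f), dev_stop()), st)
  expect_identical(out2$u, orig)
})

test_that("k_print writes one line of global expressions per firing", {
  f <- withr::local_tempfile(fileext = ".txt")
  st <- sim_state(nx = 4, ny = 1, nv = 1,
                  globals = list(T = 0, force = 0, signal = 0, end = 0))
  ring <- list(
    dev_k_func("T = t*0.5; force = t; signal = 2*t; end = ge(t,2)",
               nowhere = TRUE),
    dev_k_print(c("T", "force", "signal"), file = f),
    dev_stop(when = "end"))
  run_ring(ring, st)
  lines <- readLines(f)
  expect_length(lines, 3)
  vals <- as.numeric(strsplit(lines[3], " +")[[1]])
  expect_equal(vals, c(1, 2, 4))
})

test_that("phase-distribution initial conditions interpolate the recording", {
  tab <- cbind(c(0, 1, 2, 3), c(10, 11, 12, 13))
  st <- sim_state(nx = 4, ny = 1, nv = 2)
  ph0 <- array(0, dim = c(4, 1, 1))
  st0 <- phase_distribution_ic(tab, ph0, st)
  expect_true(all(st0$u[, , , 1] == 0) && all(st0$u[, , , 2] == 10))
  # phase k/n reproduces row k verbatim
  st1 <- phase_distribution_ic(tab, ph0 + 2 / 4, st)
  expect_true(all(st1$u[, , , 1] == 2))
  # phase 0.5/n is the midpoint of rows 0 and 1
  st2 <- phase_distribution_ic(tab, ph0 + 0.5 / 4, st)
  expect_true(all(st2$u[, , , 1] == 0.5) && all(st2$u[, , , 2] == 10.5))
  # wrap-around: phase just below 1 interpolates rows n-1 and 0
  st3 <- phase_distribution_ic(tab, ph0 + 3.5 / 4, st)
  expect_true(all(st3$u[, , , 1] == 1.5))
  expect_error(phase_distribution_ic(tab, ph0, st, layers = 0), "layer count")
})

test_that("the exponential-solver device matches direct ionic stepping", {
  # single tissue node (3x3 grid with rind): a clamped-current HH cell
  st <- sim_state(nx = 3, ny = 3, nv = 4, globals = list(end = 0))
  rest <- hh_rest_state()
  for (v in 1:4) st$u[2, 2, 1, v] <- rest[v]
  ring <- list(
    dev_k_func("end = ge(t,99)", nowhere = TRUE),
    dev_rushlarsen(v0 = 0, v1 = 3, ht = 0.02, ionic = "hh",
                   par = list(I = 8), vmin = -100, vmax = 60, ntab = 5000),
    dev_stop(when = "end"))
  out <- run_ring(ring, st)
  hh <- get_model("hh")
  tab <- ionic_tables(hh, k = 0.02, vmin = -100, vmax = 60, n = 5000)
  s <- rest
  for (i in 1:100) s <- ionic_step(s, hh, list(I = 8), 0.02, tables = tab)
  expect_equal(out$u[2, 2, 1, ], s, tolerance = 1e-12)
})

test_that("the elliptic device solves in place with a warm start", {
  g <- make_disk(1, 0.25)
  st <- sim_state(nv = 2, geom = g, globals = list(end = 0))
  st$u[, , 1, 1] <- 0                      # zero source
  ring <- list(
    dev_k_func("end = ge(t,0)", nowhere = TRUE),
    dev_elliptic(v0 = 0, v1 = 1, Dpar = 10, Dtrans = 2.2, hx = 0.25,
                 xpin = 5, ypin = 5, upin = 0.4, tolerance = 1e-9,
                 vcycles = 60),
    dev_stop(when = "end"))
  out <- suppressWarnings(run_ring(ring, st))
  tis <- g$status != 0
  expect_equal(out$u[, , 1, 2][tis], rep(0.4, sum(tis)), tolerance = 1e-8)
})

test_that("rings are deterministic and order-sensitive", {
  mkring <- function(swap = FALSE) {
    a <- dev_diffstep(v0 = 0, v1 = 2, Dpar = 1, hx = 0.5, ht = 0.02)
    b <- dev_euler(v0 = 0, v1 = 1, ht = 0.02, ode = "fhncub",
                   par = list(eps = 0.3, bet = 0.71, gam = 0.5))
    list(dev_k_func("first = eq(t,0); end = ge(t,30)", nowhere = TRUE,
                    name = "timing"),
         dev_k_func("u0 = gt(x,6)", when = "first", name = "IC"),
         if (swap) b else a,
         if (swap) a else b,
         dev_stop(when = "end"))
  }
  st <- function() sim_state(nx = 14, ny = 6, nv = 3,
                             globals = list(first = 1, end = 0))
  r1 <- run_ring(mkring(), st())
  r2 <- run_ring(mkring(), st())
  expect_identical(r1$u, r2$u)                   # bit-identical reruns
  r3 <- run_ring(mkring(swap = TRUE), st())
  expect_false(identical(r1$u, r3$u))            # splitting order matters
})

test_that("a feedback protocol fires the stimulus Del after front arrival", {
  # excitable cable with an electrode at x = 80..84: a pulse launched at the
  # left end arrives at the electrode, the crossing detector latches the
  # arrival time, and the delay-line stimulus must switch on Del later
  ht <- 0.02; Del <- 2; Dur <- 0.2; umid <- 0.5
  logf <- withr::local_tempfile(fileext = ".txt")
  st <- sim_state(nx = 102, ny = 1, nv = 3, h = 0.4,
                  globals = list(T = 0, signal = 0, Tfront = -1e3,
                                 force = 0, begin = 0, end = 0, Tstart = 0))
  ring <- list(
    dev_k_func("T = t*0.02; begin = eq(t,0); end = ge(T,12)", nowhere = TRUE,
               name = "timing"),
    dev_k_func("u0 = ifle0(x-10, 1, 0); u1 = 0", when = "begin", name = "IC"),
    dev_reduce("max", 0, "signal",
               space = list(x0 = 80, x1 = 84, y0 = 0, y1 = 0, z0 = 0, z1 = 0)),
    dev_k_poincare("signal - 0.5", pgm = "Tfront = T", sign = 1),
    dev_k_func("force = 0.02*3*ge(T,Tstart)*ge(T,Tfront+2)*le(T,Tfront+2+0.2)",
               nowhere = TRUE, name = "feedback"),
    dev_diff(v0 = 0, v1 = 2, Dpar = 1, hx = 0.4),
    dev_k_func("u2 = u2 + force", name = "stim"),
    dev_euler(v0 = 0, v1 = 1, ht = 0.02, ode = "fhnbkl", par = list(Iu = "@2")),
    dev_k_print(c("T", "signal", "force"), file = logf),
    dev_stop(when = "end"))
  out <- run_ring(ring, st)
  log <- read.table(logf)
  names(log) <- c("T", "signal", "force")
  # the wave must actually arrive at the electrode
  expect_gt(max(log$signal), umid)
  # independent detection of the front-arrival time from the signal trace
  cross <- which(log$signal[-1] >= umid & log$signal[-nrow(log)] < umid)[1]
  T_arrival <- log$T[cross + 1]
  # the stimulus switches on Del after the latched arrival, within one step
  T_fire <- log$T[which(log$force > 0)[1]]
  expect_lte(abs(T_fire - (T_arrival + Del)), ht + 1e-9)
})
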