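# Independent explicit-Euler oracle for the coupled digestion + glycemia
# model, written as one plain loop directly from the model equations. It
# shares no code with the package integrator (separate state layout, event
# handling and delay lookup) and is only practical at small steps on short
# scenarios.
euler_oracle <- function(log, params, absorption = absorption_params(),
                         g0, i0, horizon, dt = 0.01,
                         out_times = seq(0, horizon, by = 5)) {
  p <- as.list(params)
  a <- as.list(absorption)
  bw <- log$body_weight_kg
  meals <- log$meals
  ins <- log$insulins
  n <- round(horizon / dt)
  Ghist <- numeric(n + 1)

  G <- g0; I <- i0
  mono <- lip <- pro <- fib <- Q <- 0
  st_s <- st_i <- st_gi <- numeric(0)     # starch portions
  S1 <- S2 <- tmx <- numeric(0)           # depots

  meal_idx <- round(meals$time / dt)
  ins_idx <- round(ins$time / dt)
  out_idx <- round(out_times / dt)
  Gout <- Iout <- rep(NA_real_, length(out_times))

  lagG <- function(td, k) {
    if (td <= 0) return(g0)
    x <- td / dt; i0_ <- floor(x); w <- x - i0_
    if (i0_ >= k) return(Ghist[k + 1])
    Ghist[i0_ + 1] * (1 - w) + Ghist[i0_ + 2] * w
  }

  for (k in 0:n) {
    t <- k * dt
    hit <- which(out_idx == k)
    if (length(hit)) { Gout[hit] <- G; Iout[hit] <- I }
    for (m in which(meal_idx == k)) {
      mono <- mono + meals$mono_g[m]
      lip <- lip + meals$lipid_g[m]
      pro <- pro + meals$protein_g[m]
      fib <- fib + meals$fiber_g[m]
      if (meals$starch_g[m] > 0) {
        st_s <- c(st_s, meals$starch_g[m]); st_i <- c(st_i, 0)
        st_gi <- c(st_gi, meals$gi[m])
      }
    }
    for (j in which(ins_idx == k)) {
      S1 <- c(S1, ins$dose_iu[j] * 6000 / bw); S2 <- c(S2, 0)
      tmx <- c(tmx, ins$t_max_I[j])
    }
    Ghist[k + 1] <- G
    if (k == n) break

    kemp <- a$kge / (1 + a$c_lipid * lip + a$c_protein * pro +
                       a$c_fiber * fib)
    hyd <- a$khyd_ref * st_gi * st_i
    appear <- a$kabs * Q
    da <- appear / 180.16 * 1000 / (p$vg * bw)
    gd <- lagG(t - p$tau_g, k)
    f <- (gd / p$g_star)^p$gamma / (1 + (gd / p$g_star)^p$gamma)
    dep <- if (length(S2)) sum(S2 / (p$vi * tmx)) else 0

    dG <- -p$kxgi * G * I + p$tgh / p$vg + da
    dI <- -p$kxi * I + (p$tigmax / p$vi) * f + dep
    dmono <- -kemp * mono
    dlip <- -kemp * lip; dpro <- -kemp * pro; dfib <- -kemp * fib
    dst_s <- -kemp * st_s
    dst_i <- kemp * st_s - hyd
    dQ <- kemp * mono + sum(hyd) - appear
    dS1 <- -S1 / tmx; dS2 <- (S1 - S2) / tmx

    G <- G + dt * dG; I <- I + dt * dI
    mono <- mono + dt * dmono
    lip <- lip + dt * dlip; pro <- pro + dt * dpro; fib <- fib + dt * dfib
    st_s <- st_s + dt * dst_s; st_i <- st_i + dt * dst_i
    Q <- Q + dt * dQ
    if (length(S1)) { S1 <- S1 + dt * dS1; S2 <- S2 + dt * dS2 }
  }
  data.frame(t = out_times, G = Gout, I = Iout)
}

# Independent periodic cubic spline: solves the cyclic linear system for the
# second derivatives at the knots and evaluates the piecewise cubic. Used as
# the oracle for the diurnal profile curve.
periodic_spline_oracle <- function(x, y, xout, period) {
  n <- length(x)
  h <- diff(c(x, x[1] + period))
  A <- matrix(0, n, n)
  rhs <- numeric(n)
  for (i in seq_len(n)) {
    im <- if (i == 1) n else i - 1
    ip <- if (i == n) 1 else i + 1
    A[i, im] <- h[im]
    A[i, i] <- 2 * (h[im] + h[i])
    A[i, ip] <- A[i, ip] + h[i]
    rhs[i] <- 6 * ((y[ip] - y[i]) / h[i] - (y[i] - y[im]) / h[im])
  }
  M <- solve(A, rhs)
  vapply(xout, function(xv) {
    u <- ((xv - x[1]) %% period) + x[1]
    i <- findInterval(u, c(x, x[1] + period), rightmost.closed = TRUE)
    i <- min(max(i, 1), n)
    ip <- if (i == n) 1 else i + 1
    s <- u - x[i]
    y[i] + s * ((y[ip] - y[i]) / h[i] - h[i] / 6 * (2 * M[i] + M[ip])) +
      s^2 * M[i] / 2 + s^3 * (M[ip] - M[i]) / (6 * h[i])
  }, numeric(1))
}
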