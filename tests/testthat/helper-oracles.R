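# Independent oracles used across the test suite. These deliberately avoid
# the package's own code paths.

# CoM of two uniform-density half segments by midpoint integration
oracle_com_two_halves <- function(m1, m2, L, n = 20000) {
  x1 <- seq(-L / 2, 0, length.out = n + 1); x1 <- (x1[-1] + x1[-(n + 1)]) / 2
  x2 <- seq(0, L / 2, length.out = n + 1); x2 <- (x2[-1] + x2[-(n + 1)]) / 2
  dm1 <- rep(m1 / n, n); dm2 <- rep(m2 / n, n)
  sum(c(x1 * dm1, x2 * dm2)) / (m1 + m2)
}

cross3 <- function(a, b) {
  c(a[2] * b[3] - a[3] * b[2],
    a[3] * b[1] - a[1] * b[3],
    a[1] * b[2] - a[2] * b[1])
}

# net tau_y from raw trace samples via explicit cross products:
# digits at their CoP (inverted from the sensor moments) + gravity of the
# halves and handle, all about the assembly CoM
oracle_net_torque_y <- function(thumb, index, object, g = 9.81) {
  M <- object$half_mass_1 + object$half_mass_2 + object$handle_mass
  x_c <- (object$half_mass_2 - object$half_mass_1) * (object$length / 4) / M
  n <- length(thumb$t)
  tau <- numeric(n)
  for (i in seq_len(n)) {
    s <- 0
    for (tr in list(thumb, index)) {
      Fv <- tr$F[i, ]
      d <- tr$calibration$pad_offset_x
      z_c <- if (abs(Fv[["x"]]) > 1e-12) {
        (tr$M[i, "y"] + d * Fv[["z"]]) / Fv[["x"]]
      } else 0
      r <- c(d - x_c, 0, z_c)
      s <- s + cross3(r, Fv)[2]
    }
    for (part in list(c(-object$length / 4, object$half_mass_1),
                      c(object$length / 4, object$half_mass_2),
                      c(0, object$handle_mass))) {
      r <- c(part[1] - x_c, 0, 0)
      s <- s + cross3(r, c(0, 0, -part[2] * g))[2]
    }
    tau[i] <- s
  }
  tau
}

# JZS Bayes factor by direct quadrature over the Cauchy effect-size prior
oracle_bf01 <- function(t, n, r = sqrt(2) / 2) {
  nu <- n - 1
  alt <- suppressWarnings(stats::integrate(
    function(d) stats::dt(t, nu, ncp = d * sqrt(n)) * stats::dcauchy(d, 0, r),
    -Inf, Inf, rel.tol = 1e-10)$value)
  stats::dt(t, nu) / alt
}

# one-way repeated-measures ANOVA from scratch (Y: subjects x levels)
oracle_rm_oneway <- function(Y) {
  n <- nrow(Y); a <- ncol(Y)
  G <- mean(Y); A <- colMeans(Y); S <- rowMeans(Y)
  SSA <- n * sum((A - G)^2)
  SSS <- a * sum((S - G)^2)
  SSE <- sum((Y - G)^2) - SSA - SSS
  list(F = (SSA / (a - 1)) / (SSE / ((a - 1) * (n - 1))),
       df1 = a - 1, df2 = (a - 1) * (n - 1))
}

# two-within-factor repeated-measures ANOVA from scratch, long balanced data
oracle_rm_twoway <- function(d, dv = "y", A = "A", B = "B",
                             id = "participant") {
  d[[A]] <- factor(d[[A]]); d[[B]] <- factor(d[[B]]); d[[id]] <- factor(d[[id]])
  a <- nlevels(d[[A]]); b <- nlevels(d[[B]]); n <- nlevels(d[[id]])
  y <- d[[dv]]
  G <- mean(y)
  mA <- tapply(y, d[[A]], mean); mB <- tapply(y, d[[B]], mean)
  mS <- tapply(y, d[[id]], mean)
  mAB <- tapply(y, list(d[[A]], d[[B]]), mean)
  mAS <- tapply(y, list(d[[A]], d[[id]]), mean)
  mBS <- tapply(y, list(d[[B]], d[[id]]), mean)
  SSA <- n * b * sum((mA - G)^2)
  SSB <- n * a * sum((mB - G)^2)
  SSS <- a * b * sum((mS - G)^2)
  SSAB <- n * sum((sweep(sweep(mAB, 1, mA), 2, mB) + G)^2)
  SSAS <- b * sum((sweep(sweep(mAS, 1, mA), 2, mS) + G)^2)
  SSBS <- a * sum((sweep(sweep(mBS, 1, mB), 2, mS) + G)^2)
  SST <- sum((y - G)^2)
  SSABS <- SST - SSA - SSB - SSS - SSAB - SSAS - SSBS
  list(
    A = list(F = (SSA / (a - 1)) / (SSAS / ((a - 1) * (n - 1))),
             df1 = a - 1, df2 = (a - 1) * (n - 1)),
    B = list(F = (SSB / (b - 1)) / (SSBS / ((b - 1) * (n - 1))),
             df1 = b - 1, df2 = (b - 1) * (n - 1)),
    AB = list(F = (SSAB / ((a - 1) * (b - 1))) /
                (SSABS / ((a - 1) * (b - 1) * (n - 1))),
              df1 = (a - 1) * (b - 1), df2 = (a - 1) * (b - 1) * (n - 1)))
}

# standard Exp-1-style object set: equal-mass bipartite halves
mwi_objects <- function() {
  list(object_spec(0.2, 0.2, appearance = c("styrofoam", "granite"), id = "sg"),
       object_spec(0.2, 0.2, appearance = c("styrofoam", "oak"), id = "so"),
       object_spec(0.2, 0.2, appearance = c("oak", "granite"), id = "og"))
}
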