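# Independent brute-force oracles. These deliberately use different
# computational routes (lm fits, direct formula evaluation, explicit
# enumeration) than the package implementations they check.

# 2x2 mixed ANOVA oracle via effect-coded least squares: the between effect
# is the squared t of the group coefficient for the subject means, the
# within/interaction effects are the squared intercept/slope t values of an
# OLS on the difference scores.
oracle_mixed_2x2 <- function(y1, y2, group) {
  g <- ifelse(group == sort(unique(group))[1], 1, -1)
  m <- (y1 + y2) / 2
  d <- y2 - y1
  fb <- summary(stats::lm(m ~ g))$coefficients["g", "t value"]^2
  fm <- summary(stats::lm(d ~ g))$coefficients
  list(between = fb,
       within = fm["(Intercept)", "t value"]^2,
       interaction = fm["g", "t value"]^2)
}

# Levene oracle: explicit one-way ANOVA on absolute deviations
oracle_levene <- function(samples) {
  z <- unlist(lapply(samples, function(x) abs(x - mean(x))))
  g <- factor(rep(seq_along(samples), lengths(samples)))
  a <- stats::anova(stats::lm(z ~ g))
  list(F = a$`F value`[1], p = a$`Pr(>F)`[1])
}

# homogeneous-sphere dipole potential: textbook (2n+1)/n Legendre series,
# coded independently of the package's shell-transfer solver
oracle_sphere_potential <- function(node, q, epos, R, sigma = 0.33, N = 300) {
  b <- sqrt(sum(node^2)); bh <- node / b
  eh <- epos / sqrt(sum(epos^2))
  x <- sum(bh * eh)
  qr <- sum(q * bh)
  s <- sqrt(max(0, 1 - x^2))
  qt_cosphi <- if (s > 1e-12) sum(q * (eh - x * bh)) / s else 0
  tot <- 0
  Pm1 <- 1; P <- x; P1m1 <- 0; P1 <- s
  for (n in 1:N) {
    tot <- tot + (2 * n + 1) / n * (b / R)^(n - 1) *
      (n * qr * P + qt_cosphi * P1)
    Pn1 <- ((2 * n + 1) * x * P - n * Pm1) / (n + 1)
    P1n1 <- if (n == 1) 3 * x * s else ((2 * n + 1) * x * P1 - (n + 1) * P1m1) / n
    Pm1 <- P; P <- Pn1; P1m1 <- P1; P1 <- P1n1
  }
  1e-9 / (4 * pi * sigma * (R * 1e-3)^2) * 1e6 * tot
}

# longest run of TRUE values, by direct enumeration
oracle_max_run <- function(x) {
  best <- 0L; cur <- 0L
  for (v in x) {
    cur <- if (v) cur + 1L else 0L
    best <- max(best, cur)
  }
  best
}

# connected components by repeated neighborhood expansion over an explicit
# distance matrix (no adjacency hashing)
oracle_components <- function(nodes, sel, radius) {
  d <- as.matrix(stats::dist(nodes[sel, , drop = FALSE]))
  n <- length(sel)
  lab <- seq_len(n)
  repeat {
    changed <- FALSE
    for (i in seq_len(n)) {
      nb <- which(d[i, ] <= radius + 1e-9)
      new <- min(lab[nb])
      if (any(lab[nb] != new)) { lab[nb] <- new; changed <- TRUE }
    }
    if (!changed) break
  }
  split(sel, lab)
}
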