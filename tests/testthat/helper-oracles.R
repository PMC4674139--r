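# Independent brute-force oracles used to validate the geometric code.

# SASA by latitude-longitude grid quadrature: a different sampling scheme
# from the package's spiral-lattice implementation.
oracle_sasa <- function(structure, chains = NULL, probe = 1.4,
                        n_theta = 30, n_phi = 60) {
  vdw <- c(C = 1.70, N = 1.55, O = 1.52, S = 1.80, P = 1.80, SE = 1.90)
  at <- structure$atoms
  if (!is.null(chains)) at <- at[at$chain %in% chains, , drop = FALSE]
  xyz <- as.matrix(at[, c("x", "y", "z")])
  r <- unname(vdw[at$elesy])
  r[is.na(r)] <- 1.70
  r <- r + probe
  th <- (seq_len(n_theta) - 0.5) * pi / n_theta
  ph <- (seq_len(n_phi) - 0.5) * 2 * pi / n_phi
  g <- expand.grid(th = th, ph = ph)
  dirs <- cbind(sin(g$th) * cos(g$ph), sin(g$th) * sin(g$ph), cos(g$th))
  w0 <- sin(g$th) * (pi / n_theta) * (2 * pi / n_phi)
  n <- nrow(xyz)
  area <- numeric(n)
  for (i in seq_len(n)) {
    p <- sweep(dirs * r[i], 2L, xyz[i, ], "+")
    acc <- rep(TRUE, nrow(p))
    for (j in seq_len(n)) {
      if (j == i) next
      if (sum((xyz[i, ] - xyz[j, ])^2) >= (r[i] + r[j])^2) next
      dj <- (p[, 1] - xyz[j, 1])^2 + (p[, 2] - xyz[j, 2])^2 +
        (p[, 3] - xyz[j, 3])^2
      acc <- acc & dj >= r[j]^2
    }
    area[i] <- r[i]^2 * sum(w0[acc])
  }
  key <- paste(at$chain, at$resno, at$insert)
  res <- tapply(area, key, sum)
  rt <- residue_table(structure, chains)
  rt$area <- as.numeric(res[paste(rt$chain, rt$resno, rt$insert)])
  rt
}

# interface by an explicit all-pairs double loop over atoms
oracle_interface <- function(complex, side1, side2, cutoff = 6) {
  at <- complex$atoms
  a1 <- at[at$chain %in% side1, , drop = FALSE]
  a2 <- at[at$chain %in% side2, , drop = FALSE]
  hit1 <- rep(FALSE, nrow(a1))
  hit2 <- rep(FALSE, nrow(a2))
  for (i in seq_len(nrow(a1))) {
    for (j in seq_len(nrow(a2))) {
      d <- sqrt((a1$x[i] - a2$x[j])^2 + (a1$y[i] - a2$y[j])^2 +
                  (a1$z[i] - a2$z[j])^2)
      if (d <= cutoff) {
        hit1[i] <- TRUE
        hit2[j] <- TRUE
      }
    }
  }
  keyfun <- function(a) paste(a$chain, a$resno, a$insert)
  list(side1 = unique(keyfun(a1)[hit1]), side2 = unique(keyfun(a2)[hit2]))
}

# coordinate-wise RMSD between two already-aligned coordinate matrices
oracle_rmsd <- function(a, b) {
  sqrt(mean(rowSums((a - b)^2)))
}

residue_keys <- function(df) paste(df$chain, df$resno, df$insert)
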