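# Shared fixtures and independent oracles. Every oracle here is a direct
# transcription of a definition, kept deliberately naive and separate from
# the package's implementation paths.

# small simulation worlds -----------------------------------------------------

tiny_cfg <- function(..., seed = 1) {
  defaults <- list(n_controls = 16L, n_patients = 16L,
                   grid_shape = c(12L, 12L, 12L), voxel_size = 4,
                   smoothing_fwhm = 8, shared_roi_center = c(5L, 8L, 7L),
                   shared_roi_radius = 2, seed = seed)
  args <- utils::modifyList(defaults, list(...))
  do.call(simulation_config, args)
}

# a deviation stack with given z matrix on a flat dummy grid
flat_stack <- function(z, provenance = "crossval-control") {
  V <- ncol(z)
  d3 <- c(V, 1L, 1L)
  mask <- array(TRUE, d3)
  deviation_stack(z, mask, sprintf("T%03d", seq_len(nrow(z))), provenance)
}

# dense GP oracle --------------------------------------------------------------

# brute-force kernel, log marginal likelihood and predictive moments computed
# with solve() and determinant(); mirrors the documented kernel and jitter.
dense_gp_oracle <- function(X, y, Xstar, theta) {
  p <- exp(theta)
  a_mu <- mean(X$age); a_sd <- sd(X$age); if (!is.finite(a_sd) || a_sd == 0) a_sd <- 1
  enc <- function(d) cbind((d$age - a_mu) / a_sd, as.numeric(d$sex == "male"))
  Xm <- enc(X); Xs <- enc(Xstar)
  kern <- function(A, B) {
    p[["sf2"]] * exp(-0.5 * outer(A[, 1], B[, 1], `-`)^2 / p[["ell"]]^2) +
      p[["wv"]] * (A %*% t(B)) + p[["bv"]]
  }
  n <- nrow(Xm)
  K <- kern(Xm, Xm) + diag(p[["nv"]], n)
  K <- K + diag(1e-8 * mean(diag(K)), n)
  Ki <- solve(K)
  lml <- as.numeric(-0.5 * t(y) %*% Ki %*% y -
                      0.5 * determinant(K)$modulus - n / 2 * log(2 * pi))
  Ks <- kern(Xs, Xm)
  kss <- p[["sf2"]] + p[["wv"]] * rowSums(Xs^2) + p[["bv"]]
  mu <- as.numeric(Ks %*% Ki %*% y)
  vl <- kss - diag(Ks %*% Ki %*% t(Ks))
  list(lml = lml, mean = mu, var_latent = vl, var_pred = vl + p[["nv"]])
}

random_theta <- function() {
  c(sf2 = log(runif(1, 0.05, 2)), ell = log(runif(1, 0.3, 3)),
    wv = log(runif(1, 0.05, 2)), bv = log(runif(1, 0.05, 2)),
    nv = log(runif(1, 0.05, 2)))
}

# multiple-testing oracles -----------------------------------------------------

# Benjamini-Hochberg by exhaustive search over all step-up cutoffs: O(m^2).
bh_reject_oracle <- function(p, q) {
  m <- length(p)
  ord <- order(p)
  kmax <- 0
  for (k in seq_len(m)) if (p[ord[k]] <= k * q / m) kmax <- k
  rej <- rep(FALSE, m)
  if (kmax > 0) rej[ord[seq_len(kmax)]] <- TRUE
  rej
}

# Holm adjusted p-values straight from the step-down definition.
holm_adjust_oracle <- function(p, m = length(p)) {
  ord <- order(p)
  adj <- numeric(length(p))
  running <- 0
  for (i in seq_along(p)) {
    val <- min(1, (m - i + 1) * p[ord[i]])
    running <- max(running, val)
    adj[ord[i]] <- running
  }
  adj
}

# TFCE oracle ------------------------------------------------------------------

# connected components of a logical 3D array, plain R flood fill
label_components_r <- function(supra, connectivity = 26) {
  d <- dim(supra)
  lab <- array(0L, d)
  nb <- expand.grid(dx = -1:1, dy = -1:1, dz = -1:1)
  nb <- nb[!(nb$dx == 0 & nb$dy == 0 & nb$dz == 0), ]
  manh <- abs(nb$dx) + abs(nb$dy) + abs(nb$dz)
  nb <- nb[manh <= c(`6` = 1, `18` = 2, `26` = 3)[as.character(connectivity)], ]
  cur <- 0L
  idx <- which(supra, arr.ind = TRUE)
  for (r in seq_len(nrow(idx))) {
    v <- idx[r, ]
    if (lab[v[1], v[2], v[3]] != 0L) next
    cur <- cur + 1L
    queue <- list(v)
    lab[v[1], v[2], v[3]] <- cur
    while (length(queue)) {
      w <- queue[[1]]; queue <- queue[-1]
      for (j in seq_len(nrow(nb))) {
        u <- w + c(nb$dx[j], nb$dy[j], nb$dz[j])
        if (any(u < 1) || any(u > d)) next
        if (supra[u[1], u[2], u[3]] && lab[u[1], u[2], u[3]] == 0L) {
          lab[u[1], u[2], u[3]] <- cur
          queue <- c(queue, list(u))
        }
      }
    }
  }
  lab
}

# threshold-sum TFCE, positive part only, naive R implementation
tfce_oracle_pos <- function(x, H, E, dh, connectivity = 26) {
  out <- array(0, dim(x))
  mx <- max(x)
  if (mx <= 0) return(out)
  for (h in seq(dh, mx, by = dh)) {
    lab <- label_components_r(x >= h, connectivity)
    if (!any(lab > 0)) next
    sizes <- tabulate(lab)
    inc <- sizes[lab[lab > 0]]^E * h^H * dh
    out[lab > 0] <- out[lab > 0] + inc
  }
  out
}

tfce_oracle <- function(x, H = 2, E = 0.5, dh, connectivity = 26) {
  tfce_oracle_pos(pmax(x, 0), H, E, dh, connectivity) -
    tfce_oracle_pos(pmax(-x, 0), H, E, dh, connectivity)
}

# misc -------------------------------------------------------------------------

md5_of <- function(paths) unname(tools::md5sum(paths))

control_cohort <- function(n, seed = 1) {
  normdev:::with_seed(seed, data.frame(
    subject_id = sprintf("C%04d", seq_len(n)),
    age = runif(n, 18, 65),
    sex = ifelse(runif(n) < 0.5, "male", "female"),
    diagnosis = "control",
    stringsAsFactors = FALSE))
}
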