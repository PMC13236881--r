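# Shared fixtures: a biosilica-sphere suspension at the bench-standard
# 1.00 g/L with 1.657e11 particles/g, and binding parameters typical of
# a protein-saturated conjugate (K_A ~ 3e7 M^-1, ~2.8e7 sites/particle).

sphere_suspension <- function(label = "S1") {
  adsorbent_suspension(1.00, 1.657e11, label = label)
}

conjugate_params <- function(K_A_per_uM = 30.49, sites = 2.80e7,
                             suspension = sphere_suspension()) {
  binding_params(K_A_per_uM, sites, suspension)
}

# Affinity-precision study design: spheres diluted so the site capacity
# is comparable to K_D (the standard design rule for estimating an
# affinity rather than titrating sites), 12 ligand levels spanning
# 0.25-3x capacity, optionally in averaged triplicates.
diluted_params <- function(K_A_per_uM = 30.49, sites = 2.80e7) {
  binding_params(K_A_per_uM, sites, adsorbent_suspension(0.005, 1.657e11))
}

affinity_design <- function(params, n_levels = 12, replicates = 1) {
  rep(seq(0.25, 3, length.out = n_levels) * params$capacity_uM,
      each = replicates)
}

# Independent brute-force oracle for the 1:1 Langmuir equilibrium:
# bisection on free ligand, no reuse of the package's quadratic root.
langmuir_bisection_oracle <- function(M_total, capacity, K_A) {
  g <- function(Mf) Mf + capacity * K_A * Mf / (1 + K_A * Mf) - M_total
  lo <- 0
  hi <- M_total
  for (i in 1:200) {
    mid <- (lo + hi) / 2
    if (g(mid) <= 0) lo <- mid else hi <- mid
  }
  Mf <- (lo + hi) / 2
  c(M_free = Mf, M_bound = M_total - Mf)
}

# Exhaustive independent scorer for contiguous-run selection: returns the
# best run by (length desc, R^2 desc, start asc) among runs meeting r2_min.
segment_oracle <- function(x, y, min_len = 4L, r2_min = 0.99) {
  n <- length(x)
  best <- NULL
  for (start in 1:(n - min_len + 1)) {
    for (end in (start + min_len - 1):n) {
      xs <- x[start:end]
      ys <- y[start:end]
      if (stats::sd(xs) == 0) next
      r2 <- if (stats::sd(ys) == 0) 1 else stats::cor(xs, ys)^2
      if (r2 < r2_min) next
      cand <- c(start = start, end = end, len = end - start + 1, r2 = r2)
      if (is.null(best) ||
          cand["len"] > best["len"] ||
          (cand["len"] == best["len"] && cand["r2"] > best["r2"]) ||
          (cand["len"] == best["len"] && cand["r2"] == best["r2"] &&
           cand["start"] < best["start"])) {
        best <- cand
      }
    }
  }
  best
}
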