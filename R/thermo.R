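# Nearest-neighbor duplex energetics.
#
# Unified oligonucleotide NN parameters (SantaLucia 1998): enthalpy in
# kcal/mol and entropy in cal/(mol K) per dinucleotide stack, 5'->3' on the
# strand read by the helicase. Salt dependence enters as the per-stack
# entropy correction dS' = dS + 0.368 ln[Mon+]; the divalent contribution is
# folded into an equivalent monovalent concentration
# [Mon+] = [Na+] + 3.3 sqrt([Mg2+]) (molar).

.NN_DH <- c(AA = -7.9, AT = -7.2, TA = -7.2, CA = -8.5, GT = -8.4, CT = -7.8,
            GA = -8.2, CG = -10.6, GC = -9.8, GG = -8.0)
.NN_DS <- c(AA = -22.2, AT = -20.4, TA = -21.3, CA = -22.7, GT = -22.4,
            CT = -21.0, GA = -22.2, CG = -27.2, GC = -24.4, GG = -19.9)
# complementary-stack equivalences (e.g. TT/AA reads the AA parameters)
.NN_ALIAS <- c(TT = "AA", TG = "CA", AC = "GT", AG = "CT", TC = "GA",
               CC = "GG", AA = "AA", AT = "AT", TA = "TA", CA = "CA",
               GT = "GT", CT = "CT", GA = "GA", CG = "CG", GC = "GC",
               GG = "GG")

.R_KCAL <- 1.9872e-3   # gas constant, kcal/(mol K)

#' Ionic conditions for duplex energetics
#'
#' @param na_mM monovalent (Na+) concentration in mM.
#' @param mg_mM divalent (Mg2+) concentration in mM.
#' @param temperature_C temperature in Celsius (0-100).
#' @return an `ionic_conditions` object. Defaults are the unwinding assay
#'   buffer: 50 mM NaCl, 5 mM MgCl2, 25 C.
#' @export
ionic_conditions <- function(na_mM = 50, mg_mM = 5, temperature_C = 25) {
  if (na_mM < 0 || mg_mM < 0) stop("concentrations must be >= 0")
  if (temperature_C < 0 || temperature_C > 100) {
    stop("temperature must be in [0, 100] C")
  }
  structure(list(na_mM = na_mM, mg_mM = mg_mM, temperature_C = temperature_C),
            class = "ionic_conditions")
}

# equivalent monovalent concentration (molar)
.monovalent_eq <- function(cond) {
  cond$na_mM / 1000 + 3.3 * sqrt(cond$mg_mM / 1000)
}

# opening free-energy cost of each dinucleotide stack, kBT units (positive)
.stack_costs_kbt <- function(bases, cond) {
  tK <- cond$temperature_C + 273.15
  mon <- .monovalent_eq(cond)
  if (mon <= 0) stop("need a positive ionic strength")
  di <- paste0(bases[-length(bases)], bases[-1])
  key <- .NN_ALIAS[di]
  if (anyNA(key)) stop("unknown base in sequence")
  dg_kcal <- .NN_DH[key] - tK * (.NN_DS[key] + 0.368 * log(mon)) / 1000
  -dg_kcal / (.R_KCAL * tK)   # stacks are stabilizing (dG < 0) -> cost > 0
}

#' Per-base-pair melting free energy profile
#'
#' G_1bp(j) is the free energy required to open base pair j, in kBT units
#' (positive = cost). Each base pair's cost is the mean of its two flanking
#' nearest-neighbor stack costs; the terminal base pairs use their single
#' available stack. Positions flagged as displaced-strand mismatches receive
#' the override energy (default 0: free to open).
#'
#' @param substrate a [hairpin_substrate()], [fork_substrate()] (its duplex),
#'   or a plain character sequence.
#' @param conditions an [ionic_conditions()].
#' @param mismatch_energy override cost (kBT) for mismatched base pairs.
#' @return a `duplex_energy_profile`: list with `g1bp` (numeric, length L),
#'   `substrate`, `conditions`.
#' @export
compute_bp_energies <- function(substrate, conditions = ionic_conditions(),
                                mismatch_energy = 0) {
  seq_chr <- if (inherits(substrate, "hairpin_substrate")) {
    substrate$stem_sequence
  } else if (inherits(substrate, "fork_substrate")) {
    substrate$duplex_sequence
  } else {
    as.character(substrate)
  }
  mm <- if (inherits(substrate, "hairpin_substrate")) {
    substrate$mismatch_positions
  } else integer(0)
  bases <- strsplit(toupper(seq_chr), "")[[1]]
  if (any(!bases %in% c("A", "C", "G", "T"))) stop("unknown base in sequence")
  L <- length(bases)
  if (L < 2) stop("need at least 2 bp for nearest-neighbor energetics")
  st <- unname(.stack_costs_kbt(bases, conditions))   # length L-1
  g <- c(st[1], (st[-1] + st[-(L - 1)]) / 2, st[L - 1])
  if (length(mm)) g[mm] <- mismatch_energy
  structure(list(g1bp = g, substrate = substrate, conditions = conditions,
                 parameter_set = "unified_NN_1998",
                 mismatch_energy = mismatch_energy),
            class = "duplex_energy_profile")
}

#' @export
print.duplex_energy_profile <- function(x, ...) {
  cat(sprintf(
    "<duplex_energy_profile: %d bp, G_1bp %.2f-%.2f kBT, %g mM Na+, %g mM Mg2+>\n",
    length(x$g1bp), min(x$g1bp), max(x$g1bp),
    x$conditions$na_mM, x$conditions$mg_mM))
  invisible(x)
}

#' Windowed duplex stability profile
#'
#' Running mean of exp(G_1bp) over a `window_bp` window (exponentiate first,
#' then average — the order matters and is pinned by tests). The value for the
#' window starting at j is reported at position j + floor(w/2).
#'
#' @param profile a [compute_bp_energies()] result.
#' @param window_bp window width in bp (default 6).
#' @return a `stability_profile`: data.frame-like list with `positions`,
#'   `values` (> 0), and `window_bp`.
#' @export
stability_profile <- function(profile, window_bp = 6L) {
  stopifnot(inherits(profile, "duplex_energy_profile"))
  w <- as.integer(window_bp)
  if (w < 1) stop("window must be >= 1")
  L <- length(profile$g1bp)
  if (w > L) stop("window exceeds sequence length")
  vals <- running_mean(exp(profile$g1bp), w)
  structure(list(positions = seq_len(L - w + 1) + floor(w / 2),
                 values = vals, window_bp = w, profile = profile),
            class = "stability_profile")
}

#' Boltzmann dwell-time ratio for an energy difference
#'
#' The ratio of expected single-step dwell times for two positions whose
#' opening costs differ by `delta_g_kbt`: exp(delta_g). A 2.0 kBT G/C-vs-A/T
#' difference gives roughly a 7-fold dwell ratio.
#'
#' @param delta_g_kbt energy difference in kBT.
#' @return dimensionless ratio.
#' @export
boltzmann_dwell_ratio <- function(delta_g_kbt) exp(delta_g_kbt)

#' Fit a sum of Gaussians (plus constant baseline) to a profile
#'
#' Least-squares fit of `y ~ b + sum_k a_k exp(-(x-c_k)^2 / (2 s_k^2))` with
#' the number of components selected by BIC from 0 up to `max_components`.
#' Initial centers are taken from local maxima of a lightly smoothed y, in
#' order of prominence. Non-convergence of a candidate fit is recorded, never
#' silently replaced.
#'
#' @param x strictly increasing abscissa (bp).
#' @param y non-negative profile values.
#' @param max_components maximum number of Gaussian components.
#' @param min_sd lower bound for component widths (bp).
#' @return a `peak_set`: list with `centers`, `widths`, `amplitudes`,
#'   `center_se`, `baseline`, `n_components`, `bic` (vector over candidate
#'   counts), `converged` (logical per candidate), `fitted`.
#' @export
fit_gaussian_peaks <- function(x, y, max_components = 5L, min_sd = 1) {
  stopifnot(length(x) == length(y), all(diff(x) > 0))
  if (any(y < 0)) stop("y must be non-negative")
  n <- length(y)
  # candidate centers: local maxima of smoothed y, by height above baseline
  ys <- if (n >= 7) stats::filter(y, rep(1 / 5, 5), sides = 2) else y
  ys[is.na(ys)] <- y[is.na(ys)]
  ys <- as.numeric(ys)
  loc <- which(diff(sign(diff(ys))) == -2) + 1
  loc <- loc[order(ys[loc], decreasing = TRUE)]
  bic <- numeric(0); fits <- list(); conv <- logical(0)
  # k = 0: constant baseline
  rss0 <- sum((y - mean(y))^2)
  bic[1] <- n * log(max(rss0, 1e-300) / n) + 1 * log(n)
  fits[[1]] <- list(k = 0, coef = c(b = mean(y)), fitted = rep(mean(y), n))
  conv[1] <- TRUE
  span <- diff(range(x))
  for (k in seq_len(max_components)) {
    if (length(loc) < k) break
    c0 <- x[loc[seq_len(k)]]
    a0 <- pmax(ys[loc[seq_len(k)]] - min(y), max(y) * 0.05)
    s0 <- rep(max(span / (6 * k), min_sd), k)
    start <- c(b = min(y), stats::setNames(a0, paste0("a", 1:k)),
               stats::setNames(c0, paste0("c", 1:k)),
               stats::setNames(s0, paste0("s", 1:k)))
    model_fun <- function(p) {
      yy <- rep(p[["b"]], n)
      for (j in 1:k) {
        yy <- yy + p[[paste0("a", j)]] *
          exp(-(x - p[[paste0("c", j)]])^2 / (2 * p[[paste0("s", j)]]^2))
      }
      yy
    }
    fit <- tryCatch(
      minpack.lm::nls.lm(
        par = start, fn = function(p) y - model_fun(as.list(p)),
        lower = c(-Inf, rep(0, k), rep(min(x), k), rep(min_sd, k)),
        upper = c(Inf, rep(Inf, k), rep(max(x), k), rep(span, k)),
        control = minpack.lm::nls.lm.control(maxiter = 200)),
      error = function(e) NULL)
    ok <- !is.null(fit) && fit$info %in% 1:4
    conv[k + 1] <- ok
    if (!ok) { bic[k + 1] <- Inf; fits[[k + 1]] <- NULL; next }
    rss <- sum(fit$fvec^2)
    p_n <- 1 + 3 * k
    bic[k + 1] <- n * log(max(rss, 1e-300) / n) + p_n * log(n)
    se <- tryCatch(sqrt(diag(solve(fit$hessian)) * rss / max(n - p_n, 1)),
                   error = function(e) rep(NA_real_, length(start)))
    fits[[k + 1]] <- list(k = k, coef = fit$par, se = se,
                          fitted = model_fun(as.list(fit$par)))
  }
  best_k <- which.min(bic) - 1
  bf <- fits[[best_k + 1]]
  if (best_k == 0) {
    out <- list(centers = numeric(0), widths = numeric(0),
                amplitudes = numeric(0), center_se = numeric(0),
                baseline = unname(bf$coef[["b"]]))
  } else {
    cc <- unlist(bf$coef[paste0("c", 1:best_k)])
    ss <- unlist(bf$coef[paste0("s", 1:best_k)])
    aa <- unlist(bf$coef[paste0("a", 1:best_k)])
    cse <- bf$se[match(paste0("c", 1:best_k), names(bf$coef))]
    ord <- order(cc)
    out <- list(centers = unname(cc[ord]), widths = unname(ss[ord]),
                amplitudes = unname(aa[ord]), center_se = unname(cse[ord]),
                baseline = unname(bf$coef[["b"]]))
  }
  out$n_components <- best_k
  out$bic <- bic
  out$converged <- conv
  out$fitted <- bf$fitted
  out$x <- x
  structure(out, class = "peak_set")
}

#' @export
print.peak_set <- function(x, ...) {
  cat(sprintf("<peak_set: %d component(s) at %s>\n", x$n_components,
              paste(sprintf("%.1f", x$centers), collapse = ", ")))
  invisible(x)
}
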