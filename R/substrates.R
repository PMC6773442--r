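# Synthetic DNA substrates: hairpins with planted GC-rich clusters, forked
# duplexes of controlled GC count, and displaced-strand mismatch variants.
#
# Coordinates are 1-based from the hairpin base: the first base pair unwound by
# the helicase is position 1 ("unwound DNA (bp)" axis). The stem sequence is
# the 5'->3' strand read by the helicase. Mismatches live on the displaced
# strand only, so they are stored as an annotation consumed by the energy
# model rather than as a second strand.

#' Construct a hairpin substrate object
#'
#' @param stem_sequence character scalar over A/C/G/T, 5'->3' strand tracked by
#'   the helicase; its length is the stem length L in bp.
#' @param name substrate label.
#' @param mismatch_positions integer vector of 1-based stem positions carrying
#'   a displaced-strand mismatch.
#' @param loop_length loop size in nt (default 4, a tetra-dT loop).
#' @return an object of class `hairpin_substrate`.
#' @export
hairpin_substrate <- function(stem_sequence, name = "hairpin",
                              mismatch_positions = integer(0),
                              loop_length = 4L) {
  stem_sequence <- toupper(stem_sequence)
  L <- nchar(stem_sequence)
  if (L <= 0) stop("stem sequence must be non-empty")
  if (grepl("[^ACGT]", stem_sequence)) stop("alphabet must be A/C/G/T")
  mismatch_positions <- sort(unique(as.integer(mismatch_positions)))
  if (length(mismatch_positions) &&
      (min(mismatch_positions) < 1 || max(mismatch_positions) > L)) {
    stop("mismatch positions must lie in [1, L]")
  }
  structure(
    list(name = name, stem_sequence = stem_sequence, length = L,
         mismatch_positions = mismatch_positions,
         loop_length = as.integer(loop_length)),
    class = "hairpin_substrate")
}

#' @export
print.hairpin_substrate <- function(x, ...) {
  cat(sprintf("<hairpin_substrate '%s': %d bp stem, %d mismatch(es)>\n",
              x$name, x$length, length(x$mismatch_positions)))
  invisible(x)
}

#' Generate a synthetic hairpin with planted GC-rich clusters
#'
#' Emulates a long DNA hairpin whose stem carries localized clusters of high
#' GC content (strong duplex stability) on a uniform background. Within each
#' cluster window the GC count is placed exactly (`round(gc_fraction * width)`
#' positions, chosen at random), so the realized per-window GC fraction is
#' within 0.5/width of the request; the background is Bernoulli.
#'
#' @param length stem length in bp.
#' @param gc_clusters list of clusters, each `list(center=, width=, gc=)`
#'   (center bp, window width bp, GC fraction in the window).
#' @param background_gc background GC probability outside clusters.
#' @param seed integer seed; the same arguments and seed give the same
#'   sequence.
#' @param name substrate label.
#' @return a [hairpin_substrate()].
#' @examples
#' hp <- make_hairpin(174, gc_clusters = list(
#'   list(center = 55, width = 10, gc = 0.9),
#'   list(center = 90, width = 10, gc = 0.9),
#'   list(center = 120, width = 10, gc = 0.9)), background_gc = 0.35, seed = 1)
#' @export
make_hairpin <- function(length, gc_clusters = list(), background_gc = 0.35,
                         seed = 1L, name = "synthetic_hairpin") {
  if (length <= 0) stop("length must be positive")
  if (background_gc < 0 || background_gc > 1) stop("background_gc in [0,1]")
  windows <- lapply(gc_clusters, function(cl) {
    stopifnot(!is.null(cl$center), !is.null(cl$width), !is.null(cl$gc))
    if (cl$gc < 0 || cl$gc > 1) stop("cluster gc fraction must be in [0,1]")
    lo <- cl$center - floor(cl$width / 2)
    hi <- lo + cl$width - 1
    if (lo < 1 || hi > length) stop("cluster does not fit inside [1, length]")
    c(lo, hi)
  })
  if (length(windows) > 1) {
    ord <- order(vapply(windows, `[`, numeric(1), 1))
    for (k in seq_len(length(windows) - 1)) {
      if (windows[[ord[k]]][2] >= windows[[ord[k + 1]]][1]) {
        stop("overlapping clusters are not allowed")
      }
    }
  }
  old <- .Random.seed_save()
  on.exit(.Random.seed_restore(old))
  set.seed(seed)
  is_gc <- stats::runif(length) < background_gc
  for (k in seq_along(windows)) {
    idx <- windows[[k]][1]:windows[[k]][2]
    n_gc <- round(gc_clusters[[k]]$gc * base::length(idx))
    is_gc[idx] <- FALSE
    is_gc[sample(idx, n_gc)] <- TRUE
  }
  gc_pool <- c("G", "C")
  at_pool <- c("A", "T")
  bases <- ifelse(is_gc, gc_pool[1 + (stats::runif(length) < 0.5)],
                  at_pool[1 + (stats::runif(length) < 0.5)])
  hairpin_substrate(paste(bases, collapse = ""), name = name)
}

# Save/restore the global RNG state so seeded constructors do not perturb the
# caller's random stream.
.Random.seed_save <- function() {
  if (exists(".Random.seed", envir = globalenv())) {
    get(".Random.seed", envir = globalenv())
  } else NULL
}
.Random.seed_restore <- function(old) {
  if (!is.null(old)) assign(".Random.seed", old, envir = globalenv())
}

#' Introduce displaced-strand mismatches into a hairpin
#'
#' A mismatch is made by replacing G with T on the displaced strand, so an
#' eligible position is one whose stem (tracking-strand) base is C. If a
#' requested position is not eligible, the nearest eligible position is
#' substituted and recorded in the `substituted` attribute. The stem sequence
#' itself is unchanged: only the annotation consumed by the energy model (a
#' mismatched pair costs nothing to open by default) is set.
#'
#' @param substrate a [hairpin_substrate()].
#' @param positions requested 1-based mismatch positions.
#' @return a new `hairpin_substrate` with `mismatch_positions` set.
#' @export
make_mismatch_variant <- function(substrate, positions) {
  stopifnot(inherits(substrate, "hairpin_substrate"))
  positions <- as.integer(positions)
  if (!length(positions)) return(substrate)
  if (min(positions) < 1 || max(positions) > substrate$length) {
    stop("mismatch position out of range")
  }
  bases <- strsplit(substrate$stem_sequence, "")[[1]]
  eligible <- which(bases == "C")
  if (!length(eligible)) stop("no eligible (stem C) positions in substrate")
  substituted <- integer(0)
  actual <- vapply(positions, function(p) {
    if (bases[p] == "C") return(p)
    near <- eligible[which.min(abs(eligible - p))]
    substituted <<- c(substituted, p)
    near
  }, integer(1))
  out <- hairpin_substrate(substrate$stem_sequence,
                           name = paste0(substrate$name, "_mm",
                                         paste(sort(actual), collapse = "_")),
                           mismatch_positions = actual,
                           loop_length = substrate$loop_length)
  attr(out, "substituted") <- substituted
  out
}

#' Construct a forked substrate object
#'
#' @param duplex_sequence 33-bp duplex segment (top strand, 5'->3').
#' @param arm_length single-stranded arm length in nt (default 21).
#' @param name substrate label.
#' @return an object of class `fork_substrate` with fields `duplex_sequence`,
#'   `arm_length`, `gc_count`, `gc_percent`.
#' @export
fork_substrate <- function(duplex_sequence, arm_length = 21L, name = NULL) {
  duplex_sequence <- toupper(duplex_sequence)
  if (nchar(duplex_sequence) != 33) stop("duplex must be 33 bp")
  if (grepl("[^ACGT]", duplex_sequence)) stop("alphabet must be A/C/G/T")
  gc_count <- sum(strsplit(duplex_sequence, "")[[1]] %in% c("G", "C"))
  gc_percent <- round(100 * gc_count / 33)
  structure(
    list(name = name %||% sprintf("gc%d", gc_percent),
         duplex_sequence = duplex_sequence, arm_length = as.integer(arm_length),
         gc_count = gc_count, gc_percent = gc_percent),
    class = "fork_substrate")
}

#' Generate a forked substrate with a given duplex GC count
#'
#' The duplex is 33 bp with exactly `gc_count` G/C pairs at seeded-random
#' positions; 12, 16 and 26 GC give the 36%, 48% and 79% GC forks used in
#' single-turnover unwinding experiments.
#'
#' @param gc_count number of G/C pairs in the 33-bp duplex (0..33).
#' @param seed integer seed.
#' @param arm_length ssDNA arm length in nt.
#' @return a [fork_substrate()].
#' @export
make_fork <- function(gc_count, seed = 1L, arm_length = 21L) {
  gc_count <- as.integer(gc_count)
  if (gc_count < 0 || gc_count > 33) stop("gc_count must be in [0, 33]")
  old <- .Random.seed_save()
  on.exit(.Random.seed_restore(old))
  set.seed(seed)
  is_gc <- rep(FALSE, 33)
  is_gc[sample(33, gc_count)] <- TRUE
  bases <- ifelse(is_gc, c("G", "C")[1 + (stats::runif(33) < 0.5)],
                  c("A", "T")[1 + (stats::runif(33) < 0.5)])
  fork_substrate(paste(bases, collapse = ""), arm_length = arm_length)
}

#' Windowed GC fraction of a sequence
#'
#' @param sequence character scalar (or substrate object).
#' @param window window width in bp.
#' @return data.frame with `position` (window center, `j + floor(w/2)` for a
#'   window starting at `j`) and `gc` (fraction).
#' @export
windowed_gc <- function(sequence, window = 10L) {
  if (inherits(sequence, "hairpin_substrate")) sequence <- sequence$stem_sequence
  if (inherits(sequence, "fork_substrate")) sequence <- sequence$duplex_sequence
  b <- strsplit(toupper(sequence), "")[[1]]
  gc <- as.numeric(b %in% c("G", "C"))
  data.frame(position = seq_len(length(b) - window + 1) + floor(window / 2),
             gc = running_mean(gc, window))
}

#' Default emulation hairpin
#'
#' A 174-bp stem with 10-bp GC-rich clusters (GC fraction 0.9) centered at
#' 55, 90 and 120 bp on a 0.35 GC background. This is a parameterized
#' stand-in for the unpublished experimental hairpin, reproducing its length
#' and the positions of its strong pause/stability clusters; it is not the
#' experimental sequence.
#'
#' @param seed integer seed.
#' @return a [hairpin_substrate()].
#' @export
default_hairpin <- function(seed = 174L) {
  make_hairpin(174,
               gc_clusters = list(list(center = 55, width = 10, gc = 0.9),
                                  list(center = 90, width = 10, gc = 0.9),
                                  list(center = 120, width = 10, gc = 0.9)),
               background_gc = 0.35, seed = seed, name = "hp174_synthetic")
}

#' Generate a reproducible set of measured traces with ground truth
#'
#' Fixture factory wiring the stochastic stepping simulator to the
#' measurement model. Each returned trace carries its ground-truth trajectory
#' (`attr(trace, "trajectory")`) for use as a test oracle.
#'
#' @param substrate a [hairpin_substrate()].
#' @param sim_config a [sim_config()]; if its prefactor `A` is `NULL` it is
#'   calibrated to `target_mean_rate` first.
#' @param meas_config a [meas_config()].
#' @param n_traces number of traces (>= 1).
#' @param seed integer seed; per-trace seeds are derived from it.
#' @param conditions ionic conditions for the energy profile.
#' @return list of `measured_trace` objects.
#' @export
generate_trace_set <- function(substrate, sim_config = sim_config(),
                               meas_config = meas_config(), n_traces = 10L,
                               seed = 1L, conditions = ionic_conditions()) {
  if (n_traces < 1) stop("n_traces must be >= 1")
  profile <- compute_bp_energies(substrate, conditions)
  if (is.null(sim_config$A)) {
    sim_config$A <- calibrate_prefactor(substrate, sim_config, profile)
  }
  seeds <- derive_seeds(seed, 2L * n_traces)
  lapply(seq_len(n_traces), function(i) {
    traj <- simulate_trajectory(substrate, sim_config, profile,
                                seed = seeds[2 * i - 1])
    render_measurement(traj, meas_config, seed = seeds[2 * i])
  })
}
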