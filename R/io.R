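# File formats: FASTA for substrates (description-line key=value annotations
# such as mm=90,104 carry mismatch positions), TSV + JSON sidecar for traces.

#' Write substrates to FASTA
#'
#' One record per substrate; mismatch positions are stored in the description
#' as `mm=90,104`, fork arms as `arms=21`.
#'
#' @param substrates a substrate or list of substrates.
#' @param path output file.
#' @return `path`, invisibly.
#' @export
write_fasta <- function(substrates, path) {
  if (inherits(substrates, c("hairpin_substrate", "fork_substrate"))) {
    substrates <- list(substrates)
  }
  seqs <- vapply(substrates, function(s) {
    if (inherits(s, "hairpin_substrate")) s$stem_sequence else s$duplex_sequence
  }, character(1))
  hdr <- vapply(substrates, function(s) {
    ann <- if (inherits(s, "hairpin_substrate")) {
      if (length(s$mismatch_positions)) {
        sprintf(" mm=%s", paste(s$mismatch_positions, collapse = ","))
      } else ""
    } else sprintf(" arms=%d", s$arm_length)
    paste0(s$name, ann)
  }, character(1))
  x <- Biostrings::DNAStringSet(seqs)
  names(x) <- hdr
  Biostrings::writeXStringSet(x, path)
  invisible(path)
}

#' Read substrates from FASTA
#'
#' Mixed-case input is normalized to upper case; an `mm=` annotation in the
#' description is parsed back into mismatch positions. Records whose
#' description carries `arms=` are read as forks (33-bp duplex), all others
#' as hairpins.
#'
#' @param path FASTA file.
#' @return list of substrate objects.
#' @export
read_fasta <- function(path) {
  x <- tryCatch(Biostrings::readDNAStringSet(path),
                error = function(e) stop("malformed FASTA: ", conditionMessage(e)))
  lapply(seq_along(x), function(i) {
    hdr <- names(x)[i]
    parts <- strsplit(hdr, "\\s+")[[1]]
    nm <- parts[1]
    kv <- parts[-1][grepl("=", parts[-1])]
    ann <- stats::setNames(
      sub("^[^=]+=", "", kv), sub("=.*$", "", kv))
    seq_chr <- toupper(as.character(x[[i]]))
    if ("arms" %in% names(ann)) {
      fork_substrate(seq_chr, arm_length = as.integer(ann[["arms"]]),
                     name = nm)
    } else {
      mm <- if ("mm" %in% names(ann)) {
        as.integer(strsplit(ann[["mm"]], ",")[[1]])
      } else integer(0)
      hairpin_substrate(seq_chr, name = nm, mismatch_positions = mm)
    }
  })
}

#' Write a measured trace (TSV + JSON sidecar)
#'
#' The TSV has unit-bearing column names (`time_s`, `extension_nm`); the
#' sidecar `<path>.json` stores the measurement config and, when present, the
#' ground-truth step ledger and simulation config.
#'
#' @param trace a `measured_trace`.
#' @param path TSV path.
#' @return `path`, invisibly.
#' @export
write_trace <- function(trace, path) {
  utils::write.table(as.data.frame(trace)[c("time_s", "extension_nm")], path,
                     sep = "\t", row.names = FALSE, quote = FALSE)
  side <- list(meas_config = unclass(attr(trace, "meas_config")))
  traj <- attr(trace, "trajectory")
  if (!is.null(traj)) {
    side$sim_config <- unclass(traj$config)
    side$seed <- traj$seed
    side$pad_s <- attr(trace, "pad_s")
    side$ledger <- traj$ledger
    side$L <- traj$L
  }
  jsonlite::write_json(side, paste0(path, ".json"), auto_unbox = TRUE,
                       digits = NA, null = "null")
  invisible(path)
}

#' Read a measured trace written by [write_trace()]
#'
#' The time column must be strictly increasing; a missing sidecar yields a
#' trace with empty provenance.
#'
#' @param path TSV path.
#' @return a `measured_trace`.
#' @export
read_trace <- function(path) {
  df <- utils::read.table(path, sep = "\t", header = TRUE)
  if (!all(c("time_s", "extension_nm") %in% names(df))) {
    stop("trace file must have time_s and extension_nm columns")
  }
  if (any(diff(df$time_s) <= 0)) stop("non-monotonic time column")
  side_path <- paste0(path, ".json")
  if (file.exists(side_path)) {
    side <- jsonlite::read_json(side_path, simplifyVector = TRUE)
    if (!is.null(side$meas_config)) {
      attr(df, "meas_config") <- do.call(meas_config, side$meas_config)
    }
    if (!is.null(side$ledger)) {
      cfg <- side$sim_config
      sc <- sim_config(model = cfg$model, n = cfg$n, A = cfg$A,
                       v_trans = cfg$v_trans,
                       target_mean_rate = cfg$target_mean_rate,
                       pause_draw = cfg$pause_draw)
      led <- as.data.frame(side$ledger)
      traj <- structure(
        list(times = c(0, led$start[-1], max(led$start + led$pause_s +
                                               led$trans_s)),
             positions = c(0, led$bp_to), L = side$L, substrate = NULL,
             config = sc, seed = side$seed, ledger = led),
        class = "trajectory")
      attr(df, "trajectory") <- traj
      attr(df, "pad_s") <- side$pad_s
    }
  }
  class(df) <- c("measured_trace", "data.frame")
  df
}
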