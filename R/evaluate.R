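# Quality assessment: the surrogate physical-plausibility gate used in place
# of an external energy function, the external Rosetta hook, and corpus-level
# distribution reports.

# Steric clash count: heavy-atom pairs closer than `cutoff` that are neither
# within one residue nor among the bonded/1-3 neighbor pairs spanning a
# peptide bond (C(i)-N(i+1), C(i)-CA(i+1), CA(i)-N(i+1), O(i)-N(i+1)).
clash_count <- function(h, cutoff = 2.5) {
  a <- h$atoms
  xyz <- as.matrix(a[, c("x", "y", "z")])
  n <- nrow(xyz)
  d <- as.matrix(stats::dist(xyz))
  close <- d < cutoff
  close[upper.tri(close, diag = TRUE)] <- FALSE
  same_res <- outer(a$residue_index, a$residue_index, `==`)
  close <- close & !same_res
  adj <- outer(a$residue_index, a$residue_index, function(i, j) abs(i - j) == 1L)
  ei <- matrix(a$elety[row(close)], n, n)   # row atom name
  ej <- matrix(a$elety[col(close)], n, n)   # column atom name
  lo <- outer(a$residue_index, a$residue_index, `<`)  # row residue earlier
  pep <- function(first, second)  # bonded/1-3 pairs across the peptide bond
    (first == "C" & second %in% c("N", "CA")) | (first %in% c("CA", "O") & second == "N")
  bonded13 <- adj & ((lo & pep(ei, ej)) | (!lo & pep(ej, ei)))
  sum(close & !bonded13)
}

#' Surrogate physical-plausibility score of a helix
#'
#' An internal stand-in for an external energy gate:
#' `score = w1 * clashes + w2 * (1 - helical Ramachandran fraction) +
#' w3 * continuity violations`, pass when the score is below the threshold.
#' The helical fraction counts residues in either the alpha_R or the alpha_L
#' box, and clashes/continuity are distance-based, so the score is invariant
#' under rigid motion and under mirror reflection. A noise-free ideal helix
#' scores 0; random coordinates fail by orders of magnitude.
#'
#' @param h an `atomic_helix`.
#' @param w1,w2,w3 term weights (defaults 10, 50, 100).
#' @param threshold pass threshold (default 100).
#' @return list with `score`, `pass`, `clashes`, `helical_fraction`,
#'   `continuity_violations`.
#' @export
surrogate_quality <- function(h, w1 = 10, w2 = 50, w3 = 100, threshold = 100) {
  L <- length(h)
  N <- atom_by_residue(h, "N"); CA <- atom_by_residue(h, "CA")
  C <- atom_by_residue(h, "C")
  cont_viol <- 0L
  if (L > 1L && !anyNA(N) && !anyNA(C)) {
    d <- sqrt(rowSums((N[-1, , drop = FALSE] - C[-L, , drop = FALSE])^2))
    cont_viol <- sum(d < 1.2 | d > 1.5)
  }
  hel <- NA_real_
  rama_ok <- tryCatch({
    m <- measure_internal(h, check_continuity = FALSE)
    defined <- m$ics$bb_mask[, "phi"] & m$ics$bb_mask[, "psi"]
    cls <- ramachandran_class(m$ics$phi[defined], m$ics$psi[defined])
    hel <- mean(cls %in% c("alpha_R", "alpha_L"))
    TRUE
  }, error = function(e) FALSE)
  if (!rama_ok) hel <- 0
  clashes <- clash_count(h)
  score <- w1 * clashes + w2 * (1 - hel) + w3 * cont_viol
  list(score = score, pass = score < threshold, clashes = clashes,
       helical_fraction = hel, continuity_violations = cont_viol)
}

#' Score helices with an external Rosetta-style executable
#'
#' Writes each helix to a PDB file and invokes the user-supplied scorer as
#' `<executable> <pdb>`, expecting the total score (REU) as the last
#' whitespace-separated number on the last non-empty output line. Structures
#' scoring below 100 REU are classified as reasonable. The scorer is an
#' external hook: when the executable is absent the scores are returned as NA
#' with a message, never an error.
#'
#' @param helices list of `atomic_helix`.
#' @param executable path to the scoring program.
#' @param threshold classification bin boundary (default 100 REU).
#' @return data.frame with `score` (REU) and `reasonable`.
#' @export
rosetta_hook <- function(helices, executable, threshold = 100) {
  out <- data.frame(score = rep(NA_real_, length(helices)),
                    reasonable = NA)
  if (is.null(executable) || !nzchar(executable) || !file.exists(executable)) {
    message("external scorer not available; REU column marked unavailable")
    return(out)
  }
  for (i in seq_along(helices)) {
    pdb <- tempfile(fileext = ".pdb")
    write_helix_pdb(helices[[i]], pdb)
    res <- tryCatch(system2(executable, shQuote(pdb), stdout = TRUE, stderr = FALSE),
                    error = function(e) character(0))
    unlink(pdb)
    res <- res[nzchar(trimws(res))]
    if (length(res)) {
      toks <- strsplit(trimws(res[length(res)]), "\\s+")[[1]]
      val <- suppressWarnings(as.numeric(toks))
      val <- val[!is.na(val)]
      if (length(val)) out$score[i] <- val[length(val)]
    }
  }
  out$reasonable <- out$score < threshold
  out
}

#' Parse a Rosetta score file
#'
#' Reads the whitespace-delimited `SCORE:` table of a standard score file and
#' returns the `total_score` column with descriptions.
#'
#' @param file path to a score file.
#' @return data.frame with `description` and `total_score`.
#' @export
parse_rosetta_scores <- function(file) {
  ln <- grep("^SCORE:", readLines(file), value = TRUE)
  if (length(ln) < 2) stop("no SCORE: table in ", file)
  toks <- strsplit(trimws(sub("^SCORE:", "", ln)), "\\s+")
  hdr <- toks[[1]]
  rows <- toks[-1]
  ts <- match("total_score", hdr)
  de <- match("description", hdr)
  if (is.na(ts)) stop("no total_score column")
  data.frame(description = vapply(rows, function(r) if (is.na(de)) "" else r[de], ""),
             total_score = vapply(rows, function(r) as.numeric(r[ts]), 0),
             stringsAsFactors = FALSE)
}

#' Corpus-level quality report for generated helices
#'
#' Compares a set of generated structures against a reference corpus:
#' position-wise sequence identity to the nearest reference record, pooled
#' phi/psi scatter, chi-angle values pooled per slot, and a 2-component
#' principal-component projection of the flattened CA coordinates (each
#' structure superposed on the first reference structure; axes fit on the
#' reference and applied to the samples).
#'
#' @param samples list of `atomic_helix` (or a `helix_corpus`).
#' @param reference a `helix_corpus`.
#' @return a `quality_report` list: `nearest_identity`, `phi_psi`
#'   (data.frame with `set` column), `chi` (data.frame slot/value/set),
#'   `pca` (list: reference scores, sample scores, variance explained).
#' @export
corpus_report <- function(samples, reference) {
  if (inherits(samples, "helix_corpus"))
    samples <- lapply(samples$records, function(r) reconstruct(r$seq, r$ics))
  stopifnot(length(samples) > 0, length(reference) > 0)
  L <- reference$L
  if (any(vapply(samples, length, 0L) != L)) stop("sample length != reference L")

  ref_seqs <- lapply(reference$records, `[[`, "seq")
  meas <- lapply(samples, function(h) measure_internal(h, check_continuity = FALSE))
  nearest <- vapply(meas, function(m)
    max(vapply(ref_seqs, function(s) sequence_identity(m$seq, s), 0)), 0)

  pp <- function(ms, set) {
    do.call(rbind, lapply(ms, function(m) {
      ok <- m$ics$bb_mask[, "phi"] & m$ics$bb_mask[, "psi"]
      data.frame(phi = m$ics$phi[ok], psi = m$ics$psi[ok], set = set)
    }))
  }
  ref_meas <- lapply(reference$records, function(r) list(ics = r$ics, seq = r$seq))
  phi_psi <- rbind(pp(meas, "generated"), pp(ref_meas, "reference"))

  chi_tab <- function(ms, set) {
    do.call(rbind, lapply(ms, function(m) {
      idx <- which(m$ics$chi_mask, arr.ind = TRUE)
      if (nrow(idx) == 0) return(NULL)
      data.frame(slot = idx[, 2], value = m$ics$chi[idx], set = set)
    }))
  }
  chi <- rbind(chi_tab(meas, "generated"), chi_tab(ref_meas, "reference"))

  ref_h <- lapply(reference$records, function(r) reconstruct(r$seq, r$ics))
  ca0 <- atom_by_residue(ref_h[[1]], "CA")
  flat_ca <- function(h) {
    ca <- atom_by_residue(h, "CA")
    as.vector(apply_superposition(superpose(ca, ca0), ca))
  }
  ref_mat <- do.call(rbind, lapply(ref_h, flat_ca))
  smp_mat <- do.call(rbind, lapply(samples, flat_ca))
  pc <- stats::prcomp(ref_mat, center = TRUE, scale. = FALSE)
  k <- min(2L, ncol(pc$rotation))
  var2 <- sum(pc$sdev[seq_len(k)]^2) / sum(pc$sdev^2)
  proj <- function(m) sweep(m, 2, pc$center) %*% pc$rotation[, seq_len(k), drop = FALSE]
  structure(list(nearest_identity = nearest, phi_psi = phi_psi, chi = chi,
                 pca = list(reference = proj(ref_mat), samples = proj(smp_mat),
                            variance_explained = var2)),
            class = "quality_report")
}

#' @export
print.quality_report <- function(x, ...) {
  cat(sprintf("<quality_report> %d samples; nearest-identity median %.1f%%; PCA var(2) %.2f\n",
              length(x$nearest_identity), stats::median(x$nearest_identity),
              x$pca$variance_explained))
  invisible(x)
}
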