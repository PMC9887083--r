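# Bidirectional mapping between (sequence, internal coordinates) and the
# fixed-size feature map the GAN consumes and produces.
#
# The map for a helix of L residues is an L x 42 block: 20 sequence channels
# (one-hot over the alphabetical amino-acid alphabet) followed by 22 angle
# channels, each of the 11 angles (phi, psi, omega, tau_n, tau_ca, tau_c,
# chi1..chi5) encoded as a (sin, cos) pair. The trigonometric encoding removes
# the +/-pi wrap the network would otherwise have to learn; a raw theta/pi
# encoding (L x 31) is available for ablation.

#' Angle channel names of the feature map
#' @format Character vector of length 11.
#' @export
ANGLE_NAMES <- c("phi", "psi", "omega", "tau_n", "tau_ca", "tau_c",
                 paste0("chi", 1:5))

# Gather the 11 angles of a helix_ics into an L x 11 value matrix + mask.
.angles_matrix <- function(ics) {
  L <- length(ics)
  vals <- cbind(ics$phi, ics$psi, ics$omega, ics$tau_n, ics$tau_ca, ics$tau_c,
                ics$chi)
  mask <- cbind(ics$bb_mask, ics$chi_mask)
  colnames(vals) <- colnames(mask) <- ANGLE_NAMES
  list(vals = vals, mask = mask)
}

.ics_from_angles <- function(vals, mask) {
  helix_ics(phi = vals[, 1], psi = vals[, 2], omega = vals[, 3],
            tau_n = vals[, 4], tau_ca = vals[, 5], tau_c = vals[, 6],
            chi = vals[, 7:11, drop = FALSE],
            bb_mask = mask[, 1:6, drop = FALSE],
            chi_mask = mask[, 7:11, drop = FALSE])
}

#' Encode a helix as a feature map
#'
#' @param seq one-letter codes (vector or string), length L.
#' @param ics matching `helix_ics`.
#' @param L expected length (defaults to `length(seq)`); mismatch is an error.
#' @param angle_encoding `"sincos"` (default) or `"raw"` (theta/pi).
#' @return a `helix_fmap`: list with `L`, `seq_block` (L x 20), `angle_block`
#'   (L x 22 for sincos, L x 11 for raw; masked entries are 0), `mask`
#'   (L x 11 logical) and `angle_encoding`.
#' @export
encode <- function(seq, ics, L = NULL, angle_encoding = c("sincos", "raw")) {
  angle_encoding <- match.arg(angle_encoding)
  seq <- .split_seq(seq)
  if (is.null(L)) L <- length(seq)
  if (length(seq) != L || length(ics) != L)
    stop("sequence/ics length differs from configured L = ", L)
  seq_block <- matrix(0, L, 20)
  seq_block[cbind(seq_len(L), match(seq, AA_ALPHABET))] <- 1
  am <- .angles_matrix(ics)
  if (angle_encoding == "sincos") {
    angle_block <- matrix(0, L, 22)
    angle_block[, seq(1, 21, by = 2)] <- sin(am$vals) * am$mask
    angle_block[, seq(2, 22, by = 2)] <- cos(am$vals) * am$mask
    colnames(angle_block) <- paste0(rep(ANGLE_NAMES, each = 2), c("_sin", "_cos"))
  } else {
    angle_block <- (am$vals / pi) * am$mask
    colnames(angle_block) <- ANGLE_NAMES
  }
  colnames(seq_block) <- AA_ALPHABET
  structure(list(L = L, seq_block = seq_block, angle_block = angle_block,
                 mask = am$mask, angle_encoding = angle_encoding),
            class = "helix_fmap")
}

#' @export
print.helix_fmap <- function(x, ...) {
  cat(sprintf("<helix_fmap> L = %d, %s angle encoding, %d channels\n",
              x$L, x$angle_encoding, 20 + ncol(x$angle_block)))
  invisible(x)
}

#' Decode a feature map into (sequence, internal coordinates)
#'
#' Total on raw generator output: per-position residue is the argmax of the
#' sequence row (ties broken toward the lowest alphabet index), each angle is
#' `atan2(sin, cos)` of its channel pair (scale-invariant, so generated pairs
#' need not lie on the unit circle). A pair of norm < 0.1 decodes as masked,
#' as do chi slots beyond the decoded residue's rotamer count.
#'
#' @param f a `helix_fmap`, or an L x 42 numeric matrix (sincos layout).
#' @param angle_encoding used when `f` is a bare matrix.
#' @return `list(seq, ics)`.
#' @export
decode <- function(f, angle_encoding = c("sincos", "raw")) {
  if (is.matrix(f)) {
    angle_encoding <- match.arg(angle_encoding)
    f <- list(L = nrow(f), seq_block = f[, 1:20, drop = FALSE],
              angle_block = f[, -(1:20), drop = FALSE],
              angle_encoding = angle_encoding)
  }
  L <- f$L
  seq <- AA_ALPHABET[apply(f$seq_block, 1, which.max)]
  if (f$angle_encoding == "sincos") {
    s <- f$angle_block[, seq(1, 21, by = 2), drop = FALSE]
    co <- f$angle_block[, seq(2, 22, by = 2), drop = FALSE]
    vals <- atan2(s, co)
    mask <- sqrt(s^2 + co^2) >= 0.1
  } else {
    vals <- wrap_angle(f$angle_block * pi)
    mask <- matrix(TRUE, L, 11)
    if (!is.null(f$mask)) mask <- f$mask
  }
  vals[!mask] <- 0
  # chi slots beyond the decoded residue's rotamer count are masked
  mask[, 7:11] <- mask[, 7:11, drop = FALSE] & default_chi_mask(seq)
  # terminal angles that are never defined
  mask[1L, c(1, 4)] <- FALSE
  mask[L, c(3, 6)] <- FALSE
  vals[!mask] <- 0
  list(seq = seq, ics = .ics_from_angles(vals, mask))
}

#' Feature map as a single L x 42 matrix
#'
#' Sequence channels first, then the interleaved (sin, cos) angle channels.
#'
#' @param f a `helix_fmap`.
#' @return numeric matrix L x 42 (L x 31 for the raw encoding).
#' @export
fmap_matrix <- function(f) cbind(f$seq_block, f$angle_block)

#' Position-wise sequence identity between equal-length sequences
#'
#' Ungapped comparison at fixed L, as used by the corpus train/test filter:
#' `100 * matches / L`. Note that for L = 14 a 6-match pair scores 42.857%,
#' which already exceeds a 42.8% threshold, so the filter keeps at most 5
#' shared positions.
#'
#' @param a,b one-letter sequences (vectors or strings) of equal length.
#' @return identity in percent.
#' @export
sequence_identity <- function(a, b) {
  a <- .split_seq(a); b <- .split_seq(b)
  if (length(a) != length(b)) stop("sequence length mismatch")
  100 * sum(a == b) / length(a)
}

#' Serialize feature maps to a flat text array with a JSON sidecar
#'
#' Writes the stacked L x C matrices of a list of feature maps as a plain
#' whitespace-delimited matrix (`<file>`) and the channel layout, L and count
#' as JSON (`<file>.json`).
#'
#' @param fmaps list of `helix_fmap`.
#' @param file output path.
#' @return invisibly `file`.
#' @export
write_fmaps <- function(fmaps, file) {
  m <- do.call(rbind, lapply(fmaps, fmap_matrix))
  utils::write.table(m, file, row.names = FALSE, col.names = FALSE)
  side <- list(n = length(fmaps), L = fmaps[[1]]$L,
               angle_encoding = fmaps[[1]]$angle_encoding,
               channels = c(AA_ALPHABET, colnames(fmaps[[1]]$angle_block)))
  jsonlite::write_json(side, paste0(file, ".json"), auto_unbox = TRUE)
  invisible(file)
}

#' @rdname write_fmaps
#' @export
read_fmaps <- function(file) {
  side <- jsonlite::read_json(paste0(file, ".json"), simplifyVector = TRUE)
  m <- as.matrix(utils::read.table(file))
  lapply(seq_len(side$n), function(i) {
    block <- m[(i - 1L) * side$L + seq_len(side$L), , drop = FALSE]
    f <- list(L = side$L, seq_block = block[, 1:20, drop = FALSE],
              angle_block = block[, -(1:20), drop = FALSE],
              mask = NULL, angle_encoding = side$angle_encoding)
    class(f) <- "helix_fmap"
    f
  })
}
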