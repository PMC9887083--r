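# Long-peptide design pipeline: split a target helix into overlapping
# fixed-length fragments, search each independently, optionally mutate, and
# join the best matches into a single full-length analog.

#' Fragment plan for a long helical target
#'
#' @param ranges list of `c(start, end)` author residue numbers, ordered;
#'   consecutive fragments must overlap by at least 2 residues.
#' @param hotspots list (same length) of hotspot residue numbers within each
#'   fragment.
#' @param mutations optional list of `list(fragment, position, new_type)`:
#'   after the search, residue at author number `position` of that fragment's
#'   best candidate is mutated to `new_type`.
#' @return a `fragment_plan`.
#' @export
fragment_plan <- function(ranges, hotspots, mutations = list()) {
  nf <- length(ranges)
  stopifnot(nf >= 1, length(hotspots) == nf)
  for (f in seq_len(nf)) {
    r <- ranges[[f]]
    stopifnot(length(r) == 2L, r[2] >= r[1])
    hs <- hotspots[[f]]
    if (length(hs) && any(hs < r[1] | hs > r[2]))
      stop("hotspot outside fragment ", f, " range [", r[1], ", ", r[2], "]")
    if (f > 1) {
      prev <- ranges[[f - 1]]
      if (r[1] <= prev[1]) stop("fragments must be ordered by start")
      ov <- prev[2] - r[1] + 1L
      if (ov < 2L) stop("fragments ", f - 1, " and ", f,
                        " overlap by ", ov, " (< 2) residues")
    }
  }
  structure(list(ranges = ranges, hotspots = hotspots, mutations = mutations),
            class = "fragment_plan")
}

#' @export
print.fragment_plan <- function(x, ...) {
  for (f in seq_along(x$ranges))
    cat(sprintf("fragment %d: %d-%d, hotspots {%s}\n", f,
                x$ranges[[f]][1], x$ranges[[f]][2],
                paste(x$hotspots[[f]], collapse = ",")))
  invisible(x)
}

#' Overlap ranges between consecutive fragments
#' @param plan a `fragment_plan`.
#' @return list of `c(start, end)` author-number overlaps.
#' @export
plan_overlaps <- function(plan) {
  nf <- length(plan$ranges)
  if (nf < 2) return(list())
  lapply(seq_len(nf - 1L), function(f)
    c(plan$ranges[[f + 1L]][1], plan$ranges[[f]][2]))
}

#' Plan overlapping fragments over a target helix
#'
#' User-specified ranges are honored verbatim; otherwise an equal-coverage
#' sliding plan of `fragment_length` windows with minimum overlap 2 is built
#' and the declared hotspots are attached to every fragment containing them
#' (each hotspot must fall inside at least one fragment).
#'
#' @param target an `atomic_helix` (author numbering respected).
#' @param fragment_length window length (the model's L).
#' @param hotspots author residue numbers of the design constraints.
#' @param ranges optional explicit list of `c(start, end)`.
#' @param mutations optional mutation list (see [fragment_plan()]).
#' @return a `fragment_plan`.
#' @export
plan_fragments <- function(target, fragment_length = 14L, hotspots = integer(0),
                           ranges = NULL, mutations = list()) {
  resno <- unique(target$atoms$resno)
  lo <- min(resno); hi <- max(resno)
  n <- hi - lo + 1L
  if (n < fragment_length) stop("target shorter than fragment_length")
  if (is.null(ranges)) {
    nf <- max(1L, ceiling((n - fragment_length) / (fragment_length - 2L)) + 1L)
    if (nf == 1L) starts <- lo
    else starts <- round(seq(lo, hi - fragment_length + 1L, length.out = nf))
    ranges <- lapply(starts, function(s) c(s, s + fragment_length - 1L))
  }
  hs_by_frag <- lapply(ranges, function(r) hotspots[hotspots >= r[1] & hotspots <= r[2]])
  orphan <- setdiff(hotspots, unlist(hs_by_frag))
  if (length(orphan))
    stop("hotspot(s) outside all fragments: ", paste(orphan, collapse = ", "))
  fragment_plan(ranges, hs_by_frag, mutations)
}

#' Mutate one residue's side chain
#'
#' Rebuilds the side chain from the topology table for the new residue type,
#' reusing the measured chi angles for slots both types share (missing slots
#' fall back to the gauche- rotamer); backbone atoms are untouched. Works on
#' both chiralities (D helices are mirrored internally).
#'
#' @param h an `atomic_helix`.
#' @param position residue index (1-based) in `h`.
#' @param new_type one-letter (or three-letter) code.
#' @return the mutated `atomic_helix`.
#' @export
mutate_residue <- function(h, position, new_type) {
  new_type <- aa_one(new_type)
  if (h$chirality == "D")
    return(mirror_transform(mutate_residue(mirror_transform(h), position, new_type)))
  L <- length(h)
  stopifnot(position >= 1, position <= L)
  rc <- residue_coords(h, position)
  if (!all(c("N", "CA", "C") %in% rownames(rc)))
    stop("residue ", position, " lacks backbone atoms")
  old_type <- helix_seq(h)[position]
  # measured chi of the old side chain, reused where the new type has slots
  old_chi <- rep(NA_real_, 5)
  defs <- .CHI_DEFS[[old_type]]
  if (!is.null(defs)) for (k in seq_along(defs)) {
    atoms <- defs[[k]]
    if (all(atoms %in% rownames(rc)))
      old_chi[k] <- dihedral_angle(rc[atoms[1], ], rc[atoms[2], ], rc[atoms[3], ],
                                   rc[atoms[4], ])
  }
  pos <- list(N = rc["N", ], CA = rc["CA", ], C = rc["C", ], O = rc["O", ])
  if (new_type != "G") {
    pos$CB <- place_atom(pos$C, pos$N, pos$CA, .BB$b_ca_cb, .deg(.BB$a_n_ca_cb),
                         .deg(.BB$d_c_n_ca_cb))
    for (e in .SIDECHAIN[[new_type]]) {
      tors <- if (is.na(e$chi)) .deg(e$fixed) else {
        base <- if (!is.na(old_chi[e$chi])) old_chi[e$chi] else .IDEAL$chi
        wrap_angle(base + .deg(e$offset))
      }
      pos[[e$name]] <- place_atom(pos[[e$a]], pos[[e$b]], pos[[e$c]],
                                  e$bond, .deg(e$angle), tors)
    }
  }
  a <- h$atoms
  keep <- a$residue_index != position
  old_rows <- a[a$residue_index == position, , drop = FALSE]
  new_rows <- data.frame(residue_index = position, resno = old_rows$resno[1],
                         resname = aa_three(new_type), elety = names(pos),
                         x = vapply(pos, `[[`, 0, 1), y = vapply(pos, `[[`, 0, 2),
                         z = vapply(pos, `[[`, 0, 3), stringsAsFactors = FALSE)
  a <- rbind(a[keep & a$residue_index < position, , drop = FALSE], new_rows,
             a[keep & a$residue_index > position, , drop = FALSE])
  rownames(a) <- NULL
  atomic_helix(a, chirality = h$chirality, chain_id = h$chain_id)
}

#' Join fragment candidates into one continuous helix
#'
#' Fragments must already live in the target frame (each placed by its
#' hotspot partial superposition) and are stitched at the midpoint of each
#' overlap: residues up to the midpoint come from the earlier fragment, the
#' rest from the later one. If the fragments' shared backbone disagrees by
#' more than `max_overlap_rmsd` the join is refused with the offending RMSD.
#' The junction geometry is idealized by re-measuring the stitched chain's
#' internal coordinates and reconstructing with ideal bond lengths, then
#' superposing back onto the stitched backbone, so the output always passes
#' the chain-continuity invariant.
#'
#' @param best list of `atomic_helix`, one per fragment, author-numbered to
#'   match the plan ranges.
#' @param plan a `fragment_plan`.
#' @param max_overlap_rmsd compatibility threshold in Angstrom (default 2).
#' @return an `atomic_helix` spanning the full plan range.
#' @export
join_fragments <- function(best, plan, max_overlap_rmsd = 2.0) {
  nf <- length(plan$ranges)
  stopifnot(length(best) == nf)
  chir <- unique(vapply(best, `[[`, "", "chirality"))
  if (length(chir) != 1) stop("fragments have mixed chirality")
  bb <- c("N", "CA", "C", "O")
  # overlap compatibility (direct RMSD, same frame)
  for (f in seq_len(nf - 1L)) {
    ov <- c(plan$ranges[[f + 1L]][1], plan$ranges[[f]][2])
    a1 <- best[[f]]$atoms; a2 <- best[[f + 1L]]$atoms
    m1 <- a1[a1$resno >= ov[1] & a1$resno <= ov[2] & a1$elety %in% bb, , drop = FALSE]
    m2 <- a2[a2$resno >= ov[1] & a2$resno <= ov[2] & a2$elety %in% bb, , drop = FALSE]
    m1 <- m1[order(m1$resno, match(m1$elety, bb)), ]
    m2 <- m2[order(m2$resno, match(m2$elety, bb)), ]
    if (nrow(m1) != nrow(m2) || nrow(m1) == 0)
      stop("fragments ", f, "/", f + 1L, " disagree on overlap atoms")
    rmsd <- sqrt(mean(rowSums((as.matrix(m1[, c("x", "y", "z")]) -
                                 as.matrix(m2[, c("x", "y", "z")]))^2)))
    if (rmsd > max_overlap_rmsd)
      stop(sprintf("fragments %d/%d incompatible: overlap backbone RMSD %.2f A > %.2f A",
                   f, f + 1L, rmsd, max_overlap_rmsd))
  }
  # stitch at the midpoint of each overlap, constrained so every hotspot is
  # contributed by the fragment whose search optimized it
  cuts <- integer(nf - 1L)          # last resno taken from fragment f
  for (f in seq_len(nf - 1L)) {
    a <- plan$ranges[[f + 1L]][1]; b <- plan$ranges[[f]][2]
    lo <- max(c(a - 1L, plan$hotspots[[f]][plan$hotspots[[f]] >= a]))
    hi <- min(c(b, plan$hotspots[[f + 1L]][plan$hotspots[[f + 1L]] <= b] - 1L))
    if (lo > hi)
      stop("fragments ", f, "/", f + 1L,
           " have conflicting hotspots inside their overlap; no stitch point")
    cuts[f] <- as.integer(floor((lo + hi) / 2))
  }
  pieces <- vector("list", nf)
  for (f in seq_len(nf)) {
    lo <- if (f == 1L) plan$ranges[[1L]][1] else cuts[f - 1L] + 1L
    hi <- if (f == nf) plan$ranges[[nf]][2] else cuts[f]
    a <- best[[f]]$atoms
    pieces[[f]] <- a[a$resno >= lo & a$resno <= hi, , drop = FALSE]
  }
  stitched <- do.call(rbind, pieces)
  stitched$residue_index <- match(stitched$resno, sort(unique(stitched$resno)))
  rownames(stitched) <- NULL
  h <- atomic_helix(stitched, chirality = chir, chain_id = best[[1]]$chain_id)
  # idealize junction bonds: re-measure (tolerant), reconstruct, re-superpose
  hL <- if (chir == "D") mirror_transform(h) else h
  m <- measure_internal(hL, check_continuity = FALSE)
  rebuilt <- reconstruct(m$seq, m$ics, chain_id = h$chain_id,
                         resno_start = min(stitched$resno))
  sp <- superpose(helix_coords(rebuilt), helix_coords(hL)[
    match(paste(rebuilt$atoms$resno, rebuilt$atoms$elety),
          paste(hL$atoms$resno, hL$atoms$elety)), , drop = FALSE])
  helix_coords(rebuilt) <- apply_superposition(sp, helix_coords(rebuilt))
  if (chir == "D") rebuilt <- mirror_transform(rebuilt)
  validate_helix(rebuilt)
  rebuilt
}

#' Design a full-length helical analog by fragment search and joining
#'
#' For each fragment of the plan: build the hotspot specification from the
#' target residues, run the latent search register-locked to the hotspots'
#' in-fragment positions, superpose the best matched candidate into the
#' target frame via its hotspot alignment, and renumber it to the fragment
#' range. Optional point mutations are applied, fragments are joined at
#' overlap midpoints, and the analog's full-length partial RMSD over all
#' declared hotspots is reported.
#'
#' @param target an `atomic_helix` (L chirality) with author numbering.
#' @param plan a `fragment_plan` over the target numbering.
#' @param model a trained `gan_model` whose L equals the fragment length.
#' @param chirality chirality of the designed analog.
#' @param budget list with `n_restarts` and `steps` per fragment search.
#' @param seed RNG seed.
#' @param max_overlap_rmsd overlap compatibility gate passed to
#'   [join_fragments()] (default 2 Angstrom; desk-scale models whose helices
#'   carry visible curvature noise may need a consciously relaxed gate).
#' @param ... further arguments to [latent_search()].
#' @return list of class `analog_design`: `analog` (`atomic_helix`),
#'   `fragment_results` (per-fragment best `search_result`),
#'   `report` (data.frame fragment/rmsd/bin), `hotspot_rmsd` (full-length
#'   partial RMSD over all hotspots).
#' @export
design_analog <- function(target, plan, model, chirality = c("L", "D"),
                          budget = list(n_restarts = 8L, steps = 200L),
                          seed = 1L, max_overlap_rmsd = 2.0, ...) {
  chirality <- match.arg(chirality)
  cfg <- model$config
  nf <- length(plan$ranges)
  resno_all <- target$atoms$resno
  frag_best <- vector("list", nf)
  rows <- vector("list", nf)
  for (f in seq_len(nf)) {
    r <- plan$ranges[[f]]
    if (r[2] - r[1] + 1L != cfg$L)
      stop("fragment ", f, " length != model L = ", cfg$L)
    missing_res <- setdiff(r[1]:r[2], resno_all)
    if (length(missing_res))
      stop("target lacks residue(s) ", paste(missing_res, collapse = ", "),
           " required by fragment ", f)
    idx <- unique(target$atoms$residue_index[resno_all >= r[1] & resno_all <= r[2]])
    frag <- subset_helix(target, idx)
    hs_pos <- match(plan$hotspots[[f]],
                    frag$atoms$resno[!duplicated(frag$atoms$residue_index)])
    spec <- hotspot_spec_from_helix(frag, hs_pos)
    res <- latent_search(model, spec, n_restarts = budget$n_restarts,
                         steps = budget$steps, seed = seed + f,
                         chirality = chirality,
                         assignments = list(sort(hs_pos)), ...)
    res <- Filter(function(x) x$matched, res)
    if (length(res) == 0L)
      stop("fragment ", f, " search found no identity-matched candidate")
    best <- res[[1]]
    # place the candidate into the target frame via its hotspot alignment
    sp <- attr(partial_rmsd(best$helix, spec, best$assignment), "superposition")
    cand <- best$helix
    helix_coords(cand) <- apply_superposition(sp, helix_coords(cand))
    cand$atoms$resno <- cand$atoms$residue_index + r[1] - 1L
    best$helix <- cand
    frag_best[[f]] <- best
    rows[[f]] <- data.frame(fragment = f, start = r[1], end = r[2],
                            rmsd = best$rmsd,
                            bin = as.character(rmsd_bin(best$rmsd, chirality)))
  }
  # optional point mutations on the placed fragments
  for (mu in plan$mutations) {
    f <- mu$fragment
    h <- frag_best[[f]]$helix
    pos <- match(mu$position, h$atoms$resno[!duplicated(h$atoms$residue_index)])
    if (is.na(pos)) stop("mutation position ", mu$position, " not in fragment ", f)
    frag_best[[f]]$helix <- mutate_residue(h, pos, mu$new_type)
  }
  analog <- if (nf == 1L) frag_best[[1L]]$helix
            else join_fragments(lapply(frag_best, `[[`, "helix"), plan,
                                max_overlap_rmsd = max_overlap_rmsd)
  # full-length check over all declared hotspots
  all_hs <- sort(unlist(plan$hotspots))
  tgt_idx <- unique(target$atoms$residue_index[resno_all %in% all_hs])
  full_spec <- hotspot_spec_from_helix(target, tgt_idx)
  ana_resno <- analog$atoms$resno[!duplicated(analog$atoms$residue_index)]
  assignment <- match(unique(resno_all[resno_all %in% all_hs]), ana_resno)
  hot_rmsd <- tryCatch(as.numeric(partial_rmsd(analog, full_spec, assignment)),
                       error = function(e) NA_real_)
  structure(list(analog = analog, fragment_results = frag_best,
                 report = do.call(rbind, rows), hotspot_rmsd = hot_rmsd),
            class = "analog_design")
}

#' @export
print.analog_design <- function(x, ...) {
  print(x$report)
  cat(sprintf("full-length hotspot RMSD: %.3f A\n", x$hotspot_rmsd))
  invisible(x)
}

#' Read / write a fragment plan as YAML
#'
#' The plan file holds `fragments:` (list of `start`, `end`,
#' `hotspots`) and optional `mutations:` (list of `fragment`, `position`,
#' `new_type`).
#'
#' @param file YAML path.
#' @return a `fragment_plan`.
#' @export
read_plan <- function(file) {
  y <- yaml::read_yaml(file)
  fragment_plan(
    ranges = lapply(y$fragments, function(f) c(f$start, f$end)),
    hotspots = lapply(y$fragments, function(f) as.integer(unlist(f$hotspots))),
    mutations = lapply(y$mutations %||% list(), function(m)
      list(fragment = m$fragment, position = m$position, new_type = m$new_type)))
}

#' @rdname read_plan
#' @param plan a `fragment_plan`.
#' @export
write_plan <- function(plan, file) {
  y <- list(fragments = lapply(seq_along(plan$ranges), function(f)
    list(start = plan$ranges[[f]][1], end = plan$ranges[[f]][2],
         hotspots = plan$hotspots[[f]])),
    mutations = plan$mutations)
  yaml::write_yaml(y, file)
  invisible(file)
}

#' Synthetic GLP-1(7-36) helix
#'
#' The 30-residue GLP-1 peptide (author numbering 7-36) built as an ideal
#' alpha-helix from its native sequence. This is a synthetic stand-in for the
#' experimentally determined receptor-bound ligand conformation, adequate as
#' a fragment-design target because the bound peptide is helical over this
#' range.
#'
#' @return an `atomic_helix` numbered 7..36.
#' @export
synthetic_glp1_helix <- function() {
  ideal_helix("HAEGTFTSDVSSYLEGQAAKEFIAWLVKGR", resno_start = 7L)
}

#' The GLP-1 three-fragment design plan
#'
#' Fragments 7-20, 12-25 and 23-36 with hotspots {7, 9, 12}, {13, 15, 19}
#' and {28, 29, 32}.
#'
#' @return a `fragment_plan`.
#' @export
glp1_plan <- function() {
  fragment_plan(ranges = list(c(7L, 20L), c(12L, 25L), c(23L, 36L)),
                hotspots = list(c(7L, 9L, 12L), c(13L, 15L, 19L), c(28L, 29L, 32L)))
}
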