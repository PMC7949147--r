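# Intermolecular contact occupancy between two chains and the
# mutant-versus-wild-type contact-reduction statistic.
#
# "Contact" defaults to interface hydrogen bonds; van der Waals heavy-atom
# proximity (default 4.5 A) and the union of both are available because
# interface destabilization can also show in vdW packing.

#' Intermolecular contact map between two selections
#'
#' Counts contacts spanning `side_a` and `side_b` in every frame.
#' `kind = "hbond"` counts donor/acceptor pairs in either direction under the
#' geometric criteria; `kind = "vdw"` counts heavy-atom pairs within
#' `vdw_cutoff`; `kind = "both"` is the per-atom-pair union. Occupancies are
#' aggregated per residue pair and per residue of `side_a` (union semantics:
#' percent of frames with at least one contact; sum semantics also recorded).
#'
#' @param traj a [trajectory()].
#' @param side_a,side_b disjoint, non-empty selections (expressions or
#'   [select_atoms()] results), e.g. the two chains of a complex.
#' @param criteria an [hbond_criteria()] (used for `"hbond"`/`"both"`).
#' @param kind `"hbond"`, `"vdw"` or `"both"`.
#' @param vdw_cutoff heavy-atom distance cutoff in Angstrom for
#'   `"vdw"`/`"both"`.
#' @return object of class `"contact_map"` with components `pairs`
#'   (residue-pair occupancy table), `atom_pairs`, `per_frame_count`,
#'   `residues_a` (per-residue union and sum occupancies over all residues of
#'   `side_a`), `n_frames`, plus the parameters.
#' @export
contact_map <- function(traj, side_a, side_b,
                        criteria = hbond_criteria(),
                        kind = c("hbond", "vdw", "both"),
                        vdw_cutoff = 4.5) {
  stopifnot(inherits(traj, "trajectory"))
  kind <- match.arg(kind)
  topo <- traj$topology
  sa <- .as_selection(topo, side_a)
  sb <- .as_selection(topo, side_b)
  if (sa$n == 0 || sb$n == 0) stop("empty side selection")
  if (length(intersect(sa$indices, sb$indices)) > 0)
    stop("side_a and side_b selections overlap")
  nf <- traj$n_frames
  el <- topo$atoms$element

  # accumulate per-atom-pair contact indicator vectors, keyed "ia:ib"
  pair_env <- new.env(parent = emptyenv())
  add_pair <- function(ia, ib, vec) {
    key <- paste0(ia, ":", ib)
    old <- pair_env[[key]]
    pair_env[[key]] <- if (is.null(old)) vec else (old | vec)
  }

  if (kind %in% c("hbond", "both")) {
    da_a <- find_donors_acceptors(topo, sa)
    da_b <- find_donors_acceptors(topo, sb)
    one_direction <- function(donors, acceptors, donor_on_a) {
      if (nrow(donors) == 0 || length(acceptors) == 0) return(invisible())
      for (r in seq_len(nrow(donors))) {
        tr <- hbond_triple(donors$heavy[r], donors$hydrogen[r], 0L)
        for (acc in acceptors) {
          tr$acceptor <- as.integer(acc)
          vec <- .bonded_frames(traj, tr, criteria)
          if (donor_on_a) add_pair(donors$heavy[r], acc, vec)
          else add_pair(acc, donors$heavy[r], vec)
        }
      }
    }
    one_direction(da_a$donors, da_b$acceptors, donor_on_a = TRUE)
    one_direction(da_b$donors, da_a$acceptors, donor_on_a = FALSE)
  }
  if (kind %in% c("vdw", "both")) {
    heavy_a <- sa$indices[el[sa$indices] != "H"]
    heavy_b <- sb$indices[el[sb$indices] != "H"]
    for (ia in heavy_a) {
      A <- matrix(traj$coords[, ia, ], ncol = 3)
      for (ib in heavy_b) {
        B <- matrix(traj$coords[, ib, ], ncol = 3)
        vec <- sqrt(rowSums((A - B)^2)) <= vdw_cutoff
        if (any(vec)) add_pair(ia, ib, vec)
      }
    }
  }

  keys <- sort(names(pair_env))
  n_pairs <- length(keys)
  contact_mat <- matrix(FALSE, nf, n_pairs)
  ia <- integer(n_pairs); ib <- integer(n_pairs)
  for (j in seq_along(keys)) {
    contact_mat[, j] <- pair_env[[keys[j]]]
    ij <- as.integer(strsplit(keys[j], ":")[[1]])
    ia[j] <- ij[1]; ib[j] <- ij[2]
  }
  per_frame_count <- if (n_pairs > 0) rowSums(contact_mat) else rep(0L, nf)

  resid <- topo$atoms$resid
  atom_pairs <- data.frame(
    atom_a = ia, atom_b = ib,
    resid_a = resid[ia], resid_b = resid[ib],
    occupancy_pct = if (n_pairs > 0) 100 * colMeans(contact_mat) else numeric(0)
  )
  atom_pairs <- atom_pairs[atom_pairs$occupancy_pct > 0, , drop = FALSE]
  rownames(atom_pairs) <- NULL

  # residue-pair union occupancy
  if (n_pairs > 0) {
    rp_key <- paste(resid[ia], resid[ib], sep = ":")
    urp <- sort(unique(rp_key))
    pairs <- do.call(rbind, lapply(urp, function(k) {
      cols <- which(rp_key == k)
      any_vec <- rowSums(contact_mat[, cols, drop = FALSE]) > 0
      rr <- as.integer(strsplit(k, ":")[[1]])
      data.frame(resid_a = rr[1], resid_b = rr[2],
                 occupancy_pct = 100 * mean(any_vec))
    }))
    pairs <- pairs[order(pairs$resid_a, pairs$resid_b), , drop = FALSE]
    rownames(pairs) <- NULL
  } else {
    pairs <- data.frame(resid_a = integer(0), resid_b = integer(0),
                        occupancy_pct = numeric(0))
  }
  pairs <- pairs[pairs$occupancy_pct > 0, , drop = FALSE]
  rownames(pairs) <- NULL

  # per-residue occupancy over ALL residues of side_a (zeros included)
  res_a_all <- sort(unique(resid[sa$indices]))
  occ_union <- numeric(length(res_a_all))
  occ_sum <- numeric(length(res_a_all))
  for (q in seq_along(res_a_all)) {
    cols <- which(resid[ia] == res_a_all[q])
    if (length(cols) > 0) {
      occ_union[q] <- 100 * mean(rowSums(contact_mat[, cols, drop = FALSE]) > 0)
      rp <- pairs[pairs$resid_a == res_a_all[q], , drop = FALSE]
      occ_sum[q] <- sum(rp$occupancy_pct)
    }
  }
  residues_a <- data.frame(resid = res_a_all, occupancy_union = occ_union,
                           occupancy_sum = occ_sum)

  structure(
    list(pairs = pairs, atom_pairs = atom_pairs,
         per_frame_count = per_frame_count, residues_a = residues_a,
         side_a = sa$expression, side_b = sb$expression,
         kind = kind, criteria = criteria, vdw_cutoff = vdw_cutoff,
         n_frames = nf),
    class = "contact_map"
  )
}

#' @export
print.contact_map <- function(x, ...) {
  cat(sprintf(
    "contact map (%s): %d residue pairs, mean %.2f contacts/frame over %d frames\n",
    x$kind, nrow(x$pairs), mean(x$per_frame_count), x$n_frames))
  invisible(x)
}

.check_comparable <- function(wt, mutant) {
  if (wt$kind != mutant$kind)
    stop("comparability error: contact maps computed with different kinds (",
         wt$kind, " vs ", mutant$kind, ")")
  if (!isTRUE(all.equal(unclass(wt$criteria), unclass(mutant$criteria))))
    stop("comparability error: contact maps computed with different H-bond criteria")
  if (wt$kind != "hbond" && wt$vdw_cutoff != mutant$vdw_cutoff)
    stop("comparability error: different vdw cutoffs")
}

#' Mutant-versus-wild-type contact reduction
#'
#' Per residue of `side_a`: `100 * (1 - occ_mut / occ_wt)` using the
#' residue's interface occupancy (union semantics by default: percent of
#' frames in which the residue makes at least one interface contact).
#' Residues with zero wild-type occupancy are masked (`NA`), never reported
#' as infinite. The overall reduction is
#' `100 * (1 - mean mutant contacts/frame / mean WT contacts/frame)`,
#' i.e. the summation of individual atom contacts per frame relative to WT.
#' Negative reductions (mutant above WT) are reported as negative, not
#' clamped.
#'
#' @param wt,mutant [contact_map()]s computed with identical criteria, kind
#'   and residue numbering on `side_a`.
#' @param semantics `"union"` (default) or `"sum"` per-residue occupancy.
#' @return object of class `"reduction_profile"`: `per_residue` data.frame
#'   (`resid`, `wt_occupancy`, `mut_occupancy`, `reduction_pct`, `masked`)
#'   and `overall_reduction` (percent).
#' @export
reduction_profile <- function(wt, mutant, semantics = c("union", "sum")) {
  stopifnot(inherits(wt, "contact_map"), inherits(mutant, "contact_map"))
  semantics <- match.arg(semantics)
  .check_comparable(wt, mutant)
  col <- paste0("occupancy_", semantics)
  res <- sort(union(wt$residues_a$resid, mutant$residues_a$resid))
  occ_of <- function(map, r) {
    i <- match(r, map$residues_a$resid)
    ifelse(is.na(i), 0, map$residues_a[[col]][i])
  }
  wt_occ <- vapply(res, function(r) occ_of(wt, r), numeric(1))
  mut_occ <- vapply(res, function(r) occ_of(mutant, r), numeric(1))
  masked <- wt_occ == 0
  red <- ifelse(masked, NA_real_, 100 * (1 - mut_occ / wt_occ))
  mean_wt <- mean(wt$per_frame_count)
  mean_mut <- mean(mutant$per_frame_count)
  overall <- if (mean_wt == 0) {
    warning("wild-type map has no contacts; overall reduction undefined")
    NA_real_
  } else {
    100 * (1 - mean_mut / mean_wt)
  }
  structure(
    list(per_residue = data.frame(resid = res, wt_occupancy = wt_occ,
                                  mut_occupancy = mut_occ,
                                  reduction_pct = red, masked = masked),
         overall_reduction = overall, semantics = semantics),
    class = "reduction_profile"
  )
}

#' @export
print.reduction_profile <- function(x, ...) {
  cat(sprintf("reduction profile: overall %.1f%%, %d residues (%d masked)\n",
              x$overall_reduction, nrow(x$per_residue),
              sum(x$per_residue$masked)))
  invisible(x)
}

#' Highest-occupancy contact residues ("groove" report)
#'
#' Ranks the contacting residues of `side_a` by summed interface occupancy,
#' descending; ties broken by ascending residue number. Residues without any
#' contact are omitted.
#'
#' @param map a [contact_map()].
#' @param top_n number of residues to report (>= 1).
#' @return data.frame `resid`, `total_occupancy_pct` with at most `top_n`
#'   rows.
#' @export
groove_report <- function(map, top_n = 10) {
  stopifnot(inherits(map, "contact_map"))
  if (top_n < 1) stop("top_n must be >= 1")
  df <- map$residues_a[map$residues_a$occupancy_sum > 0, , drop = FALSE]
  df <- df[order(-df$occupancy_sum, df$resid), , drop = FALSE]
  out <- data.frame(resid = df$resid, total_occupancy_pct = df$occupancy_sum)
  utils::head(out, top_n)
}

#' Write a contact map's residue-pair table as TSV
#' @param map a [contact_map()].
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_contact_tsv <- function(map, path) {
  comments <- c(
    sprintf("kind: %s", map$kind),
    sprintf("max_da_distance_A: %g", map$criteria$max_da_distance),
    sprintf("min_dha_angle_deg: %g", map$criteria$min_dha_angle),
    sprintf("vdw_cutoff_A: %g", map$vdw_cutoff),
    sprintf("n_frames: %d", map$n_frames),
    sprintf("mean_contacts_per_frame: %.6f", mean(map$per_frame_count))
  )
  .write_tsv(map$pairs, path, comments)
}

#' Write a per-residue reduction table as TSV
#' @param profile a [reduction_profile()].
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_reduction_tsv <- function(profile, path) {
  comments <- c(
    sprintf("overall_reduction_pct: %.6f", profile$overall_reduction),
    sprintf("semantics: %s", profile$semantics),
    sprintf("masked_residues: %s",
            paste(profile$per_residue$resid[profile$per_residue$masked],
                  collapse = " "))
  )
  .write_tsv(profile$per_residue, path, comments)
}
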