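#' Residue-wise interaction-energy profile
#'
#' Each residue's energy is the sum of its unmasked pairwise interactions
#' with every other residue, so the profile total equals twice the sum over
#' unmasked unordered pairs (each pair contributes to both partners).
#'
#' @param mat \code{avg_energy} or \code{pairwise_energy}
#' @return data.frame with \code{chain_id}, \code{residue_number},
#'   \code{energy} (kcal/mol) and, when replicate sems are available,
#'   \code{sem}
#' @export
residue_wise <- function(mat) {
  m <- if (inherits(mat, "avg_energy")) mat$mean else mat$total
  m[mat$mask] <- 0
  out <- mat$residues[, c("chain_id", "residue_number")]
  out$energy <- rowSums(m)
  if (inherits(mat, "avg_energy")) {
    s <- mat$sem; s[mat$mask] <- 0
    out$sem <- sqrt(rowSums(s^2))
  }
  rownames(out) <- NULL
  out
}

# assign each residue to a segment/loop group; unassigned -> "other"
assign_groups <- function(residues, definition) {
  segs <- reporting_segments(definition, tm_only = FALSE)
  grp <- rep("other", nrow(residues))
  for (nm in names(segs)) {
    r <- segs[[nm]]
    grp[residues$residue_number >= r[1] & residues$residue_number <= r[2]] <- nm
  }
  factor(grp, levels = c(names(segs), if (any(grp == "other")) "other"))
}

#' Helix/loop group energy matrix
#'
#' Aggregates unmasked residue-pair energies into segment-level groups
#' (pivoted helices contribute as their two compartments).  Entry (A, B) is
#' the sum over unmasked pairs with one residue in A and one in B; the
#' diagonal holds within-group pair sums.  The grand total over distinct
#' group pairs plus the diagonal equals the matrix's unmasked pair total
#' (conservation).
#'
#' @param mat \code{avg_energy} or \code{pairwise_energy}
#' @param definition \code{segment_definition}
#' @return object of class \code{group_energy}: \code{groups},
#'   \code{energy} (symmetric matrix), \code{n_other} unassigned residues
#' @export
group_matrix <- function(mat, definition) {
  m <- if (inherits(mat, "avg_energy")) mat$mean else mat$total
  m[mat$mask] <- 0
  grp <- assign_groups(mat$residues, definition)
  if (any(grp == "other"))
    message(sum(grp == "other"), " residue(s) outside all segments collected into group 'other'")
  lev <- levels(grp)
  ind <- outer(grp, lev, `==`) * 1            # residues x groups indicator
  g <- t(ind) %*% m %*% ind
  # within-group: each unordered pair counted twice by the double aggregation
  diag(g) <- diag(g) / 2
  structure(list(groups = lev, energy = unname(g),
                 n_other = sum(grp == "other")),
            class = "group_energy")
}

#' @export
print.group_energy <- function(x, ...) {
  cat("<group_energy>", length(x$groups), "groups\n")
  m <- x$energy
  dimnames(m) <- list(x$groups, x$groups)
  print(round(m, 3))
  invisible(x)
}

#' Wildtype-vs-mutant difference network
#'
#' Per-pair energy change \code{delta = E_mut - E_wt} on the shared residue
#' universe (mutated residues are matched by residue number and flagged, not
#' excluded).  Replicate dispersion is combined in quadrature:
#' \code{sem_delta = sqrt(sem_wt^2 + sem_mut^2)}.  Pairs are classified by
#' sign: attractive-lost (wt attractive, delta > 0), attractive-gained
#' (mutant attractive, delta < 0), repulsive-gained (mutant repulsive,
#' delta > 0), repulsive-lost (wt repulsive, delta < 0).
#'
#' @param wt,mut \code{avg_energy} objects on matching residue numbers
#' @param mutated_residues residue numbers carrying the mutation (flagged)
#' @return object of class \code{diff_network}: \code{residues},
#'   \code{delta}, \code{sem}, \code{wt_mean}, \code{mut_mean}, \code{mask},
#'   \code{mutated}
#' @export
diff_network <- function(wt, mut, mutated_residues = integer(0)) {
  if (!identical(wt$residues$residue_number, mut$residues$residue_number) ||
      !identical(wt$residues$chain_id, mut$residues$chain_id))
    stop("wildtype and mutant residue sets cannot be aligned by residue number")
  wt_m <- if (inherits(wt, "avg_energy")) wt$mean else wt$total
  mut_m <- if (inherits(mut, "avg_energy")) mut$mean else mut$total
  wt_s <- if (inherits(wt, "avg_energy")) wt$sem else 0 * wt_m
  mut_s <- if (inherits(mut, "avg_energy")) mut$sem else 0 * mut_m
  mask <- wt$mask | mut$mask
  structure(list(residues = wt$residues,
                 delta = mut_m - wt_m,
                 sem = sqrt(wt_s^2 + mut_s^2),
                 wt_mean = wt_m, mut_mean = mut_m, mask = mask,
                 mutated = wt$residues$residue_number %in% mutated_residues),
            class = "diff_network")
}

#' @export
print.diff_network <- function(x, ...) {
  d <- abs(x$delta); d[x$mask] <- 0
  cat(sprintf("<diff_network> %d residues; max |delta| = %.3f kcal/mol\n",
              nrow(x$residues), max(d)))
  invisible(x)
}

#' Sign classification of difference-network pairs
#' @param dn \code{diff_network}
#' @return character matrix with entries "attractive-lost",
#'   "attractive-gained", "repulsive-gained", "repulsive-lost" or "unchanged"
#' @export
classify_diff <- function(dn) {
  cls <- matrix("unchanged", nrow(dn$delta), ncol(dn$delta))
  up <- dn$delta > 0
  dn_ <- dn$delta < 0
  cls[up & dn$wt_mean < 0] <- "attractive-lost"
  cls[up & dn$wt_mean >= 0] <- "repulsive-gained"
  cls[dn_ & dn$mut_mean < 0] <- "attractive-gained"
  cls[dn_ & dn$mut_mean >= 0] <- "repulsive-lost"
  cls
}

#' Pairs of a difference network above a threshold
#'
#' @param dn \code{diff_network}
#' @param threshold kcal/mol on |delta| (default 0.5)
#' @return data.frame res_i, res_j, delta, sem, class, sorted by |delta|
#' @export
diff_pairs <- function(dn, threshold = 0.5) {
  lab <- res_label(dn$residues)
  cls <- classify_diff(dn)
  ut <- which(upper.tri(dn$delta) & !dn$mask & abs(dn$delta) >= threshold,
              arr.ind = TRUE)
  out <- data.frame(res_i = lab[ut[, 1]], res_j = lab[ut[, 2]],
                    delta = dn$delta[ut], sem = dn$sem[ut],
                    class = cls[ut], stringsAsFactors = FALSE)
  out <- out[order(-abs(out$delta)), ]
  rownames(out) <- NULL
  out
}

#' Residues most affected by a mutation
#'
#' Compares wildtype and mutant residue-wise profiles and returns residues
#' whose absolute energy change meets the threshold, ranked by |delta|.
#' The default threshold of 1.0 kcal/mol is a package convention (reported
#' alongside the result), not a universal constant.
#'
#' @param wt,mut residue-wise profiles (\code{\link{residue_wise}}) on the
#'   same residues
#' @param threshold kcal/mol on |delta residue-wise energy| (default 1.0)
#' @return data.frame with \code{residue_number}, \code{chain_id},
#'   \code{wt}, \code{mut}, \code{delta}, \code{rank}; attribute
#'   \code{"threshold"}
#' @export
significant_residues <- function(wt, mut, threshold = 1.0) {
  if (!identical(wt$residue_number, mut$residue_number))
    stop("profiles are not on matching residues")
  delta <- mut$energy - wt$energy
  keep <- abs(delta) >= threshold
  out <- data.frame(residue_number = wt$residue_number[keep],
                    chain_id = wt$chain_id[keep],
                    wt = wt$energy[keep], mut = mut$energy[keep],
                    delta = delta[keep])
  out <- out[order(-abs(out$delta)), ]
  out$rank <- seq_len(nrow(out))
  rownames(out) <- NULL
  attr(out, "threshold") <- threshold
  out
}
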