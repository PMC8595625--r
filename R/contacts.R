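# Donor/acceptor typing for standard residues.
# Donors are heavy atoms with attached polar hydrogens (hydrogen names listed
# so the D-H...A angle can be evaluated when hydrogens are present);
# acceptors are lone-pair-bearing heavy atoms.

hbond_donors <- function() {
  rbind(
    data.frame(residue_name = "*",   donor = "N",   hydrogens = "H", stringsAsFactors = FALSE),
    data.frame(residue_name = "SER", donor = "OG",  hydrogens = "HG"),
    data.frame(residue_name = "THR", donor = "OG1", hydrogens = "HG1"),
    data.frame(residue_name = "TYR", donor = "OH",  hydrogens = "HH"),
    data.frame(residue_name = "CYS", donor = "SG",  hydrogens = "HG1"),
    data.frame(residue_name = "ASN", donor = "ND2", hydrogens = "HD21,HD22"),
    data.frame(residue_name = "GLN", donor = "NE2", hydrogens = "HE21,HE22"),
    data.frame(residue_name = "LYS", donor = "NZ",  hydrogens = "HZ1,HZ2,HZ3"),
    data.frame(residue_name = "ARG", donor = "NE",  hydrogens = "HE"),
    data.frame(residue_name = "ARG", donor = "NH1", hydrogens = "HH11,HH12"),
    data.frame(residue_name = "ARG", donor = "NH2", hydrogens = "HH21,HH22"),
    data.frame(residue_name = "TRP", donor = "NE1", hydrogens = "HE1"),
    data.frame(residue_name = "HIS", donor = "ND1", hydrogens = "HD1"),
    data.frame(residue_name = "HIS", donor = "NE2", hydrogens = "HE2"))
}

hbond_acceptors <- function() {
  rbind(
    data.frame(residue_name = "*",   acceptor = "O", stringsAsFactors = FALSE),
    data.frame(residue_name = "*",   acceptor = "OXT"),
    data.frame(residue_name = "SER", acceptor = "OG"),
    data.frame(residue_name = "THR", acceptor = "OG1"),
    data.frame(residue_name = "TYR", acceptor = "OH"),
    data.frame(residue_name = "ASN", acceptor = "OD1"),
    data.frame(residue_name = "GLN", acceptor = "OE1"),
    data.frame(residue_name = "ASP", acceptor = "OD1"),
    data.frame(residue_name = "ASP", acceptor = "OD2"),
    data.frame(residue_name = "GLU", acceptor = "OE1"),
    data.frame(residue_name = "GLU", acceptor = "OE2"),
    data.frame(residue_name = "HIS", acceptor = "ND1"),
    data.frame(residue_name = "HIS", acceptor = "NE2"),
    data.frame(residue_name = "MET", acceptor = "SD"))
}

# charged side-chain groups for salt-bridge detection
charged_groups <- function() {
  list(negative = list(ASP = c("OD1", "OD2"), GLU = c("OE1", "OE2")),
       positive = list(LYS = "NZ", ARG = c("NE", "NH1", "NH2"),
                       HIS = c("ND1", "NE2")))
}

#' Hydrogen-bond detection criteria
#' @param d_max maximum donor-acceptor heavy-atom distance, Angstrom
#' @param theta_min minimum D-H...A angle, degrees (ignored when the donor
#'   has no hydrogen in the structure; distance-only mode is then reported)
#' @return list of criteria
#' @export
hbond_criteria <- function(d_max = 3.5, theta_min = 120) {
  stopifnot(d_max > 0, theta_min >= 0, theta_min <= 180)
  list(d_max = d_max, theta_min = theta_min)
}

as_traj <- function(x) {
  if (inherits(x, "helix_trajectory")) return(x)
  if (inherits(x, "helix_structure"))
    return(new_trajectory(x, matrix(as.numeric(t(x$coords)), nrow = 1)))
  stop("expected a helix_structure or helix_trajectory")
}

angle_deg <- function(a, b, c) {
  # angle at b between rays b->a and b->c
  u <- a - b; v <- c - b
  cosang <- sum(u * v) / sqrt(sum(u^2) * sum(v^2))
  acos(max(-1, min(1, cosang))) * 180 / pi
}

#' Detect hydrogen bonds over a trajectory
#'
#' Geometric criterion evaluated per frame: donor-acceptor heavy-atom
#' distance at most \code{d_max} and, when the donor's hydrogen is present,
#' D-H...A angle at least \code{theta_min} (any attached hydrogen may
#' qualify).  Donors without hydrogens fall back to distance-only detection,
#' flagged in the output.  Intra-residue pairs are skipped.  Occupancy is the
#' fraction of frames satisfying the criterion.
#'
#' @param x \code{helix_trajectory} or single \code{helix_structure}
#' @param candidates optional two-column matrix/data.frame of residue-number
#'   pairs to restrict the search
#' @param criteria \code{\link{hbond_criteria}}
#' @return data.frame of contacts with occupancy > 0: kind, donor/acceptor
#'   residue and atom ids, mean distance over qualifying frames, mean angle
#'   (NA in distance-only mode), occupancy, angle_checked
#' @export
detect_hbonds <- function(x, candidates = NULL, criteria = hbond_criteria()) {
  traj <- as_traj(x)
  top <- traj$topology
  a <- top$atoms
  unknown <- setdiff(unique(a$residue_name), STANDARD_AA)
  if (length(unknown))
    stop("unknown residue type(s) for donor/acceptor typing: ",
         paste(unknown, collapse = ", "))
  don_tab <- hbond_donors(); acc_tab <- hbond_acceptors()
  res_of <- paste(a$chain_id, a$residue_number)
  donors <- which(paste(a$residue_name, a$atom_name) %in%
                    paste(don_tab$residue_name, don_tab$donor) |
                  a$atom_name %in% don_tab$donor[don_tab$residue_name == "*"])
  acceptors <- which(paste(a$residue_name, a$atom_name) %in%
                       paste(acc_tab$residue_name, acc_tab$acceptor) |
                     a$atom_name %in% acc_tab$acceptor[acc_tab$residue_name == "*"])
  if (!length(donors) || !length(acceptors)) return(empty_contacts())
  # attached hydrogens per donor atom index
  hyd_of <- lapply(donors, function(d) {
    row <- don_tab[(don_tab$residue_name == a$residue_name[d] |
                    don_tab$residue_name == "*") & don_tab$donor == a$atom_name[d], ]
    hn <- unlist(strsplit(row$hydrogens, ","))
    which(res_of == res_of[d] & a$atom_name %in% hn)
  })
  pairs <- expand.grid(d = donors, ac = acceptors)
  pairs <- pairs[res_of[pairs$d] != res_of[pairs$ac], , drop = FALSE]
  if (!is.null(candidates)) {
    candidates <- as.matrix(candidates)
    want <- paste(pmin(candidates[, 1], candidates[, 2]),
                  pmax(candidates[, 1], candidates[, 2]))
    pr <- paste(pmin(a$residue_number[pairs$d], a$residue_number[pairs$ac]),
                pmax(a$residue_number[pairs$d], a$residue_number[pairs$ac]))
    pairs <- pairs[pr %in% want, , drop = FALSE]
  }
  if (!nrow(pairs)) return(empty_contacts())
  nf <- n_frames(traj)
  hits <- matrix(FALSE, nf, nrow(pairs))
  dsum <- matrix(0, nf, nrow(pairs)); asum <- matrix(NA_real_, nf, nrow(pairs))
  for (f in seq_len(nf)) {
    co <- frame_coords(traj, f)
    for (k in seq_len(nrow(pairs))) {
      d <- pairs$d[k]; ac <- pairs$ac[k]
      dist <- sqrt(sum((co[d, ] - co[ac, ])^2))
      dsum[f, k] <- dist
      if (dist > criteria$d_max) next
      hs <- hyd_of[[match(d, donors)]]
      if (length(hs)) {
        angs <- vapply(hs, function(h) angle_deg(co[d, ], co[h, ], co[ac, ]),
                       numeric(1))
        best <- max(angs)
        asum[f, k] <- best
        hits[f, k] <- best >= criteria$theta_min
      } else {
        hits[f, k] <- TRUE                      # distance-only mode
      }
    }
  }
  occ <- colMeans(hits)
  keep <- which(occ > 0)
  if (!length(keep)) return(empty_contacts())
  out <- do.call(rbind, lapply(keep, function(k) {
    d <- pairs$d[k]; ac <- pairs$ac[k]; q <- hits[, k]
    data.frame(kind = "hbond",
               donor_residue = a$residue_number[d], donor_atom = a$atom_name[d],
               acceptor_residue = a$residue_number[ac],
               acceptor_atom = a$atom_name[ac],
               distance = mean(dsum[q, k]),
               angle = if (all(is.na(asum[q, k]))) NA_real_
                       else mean(asum[q, k], na.rm = TRUE),
               occupancy = occ[k],
               angle_checked = length(hyd_of[[match(d, donors)]]) > 0,
               stringsAsFactors = FALSE)
  }))
  rownames(out) <- NULL
  out
}

empty_contacts <- function() {
  data.frame(kind = character(), donor_residue = integer(),
             donor_atom = character(), acceptor_residue = integer(),
             acceptor_atom = character(), distance = numeric(),
             angle = numeric(), occupancy = numeric(),
             angle_checked = logical(), stringsAsFactors = FALSE)
}

#' Detect salt bridges over a trajectory
#'
#' A contact is recorded for a frame when the minimum distance between the
#' charged-group heavy atoms of an oppositely charged residue pair
#' (Asp/Glu carboxylate oxygens vs Lys NZ, Arg NE/NH1/NH2, His ring
#' nitrogens) is at most \code{cutoff}.  Same-sign pairs are never reported.
#'
#' @param x \code{helix_trajectory} or \code{helix_structure}
#' @param cutoff Angstrom (default 4.0)
#' @return data.frame of contacts: kind, residue ids, the closest atom pair
#'   at minimum mean distance, mean minimum distance over qualifying frames,
#'   occupancy
#' @export
detect_salt_bridges <- function(x, cutoff = 4.0) {
  stopifnot(cutoff > 0)
  traj <- as_traj(x)
  a <- traj$topology$atoms
  unknown <- setdiff(unique(a$residue_name), STANDARD_AA)
  if (length(unknown))
    stop("unknown residue type(s) for charge typing: ",
         paste(unknown, collapse = ", "))
  cg <- charged_groups()
  pick <- function(side) {
    idx <- integer(0)
    for (rn in names(side))
      idx <- c(idx, which(a$residue_name == rn & a$atom_name %in% side[[rn]]))
    idx
  }
  neg <- pick(cg$negative); pos <- pick(cg$positive)
  if (!length(neg) || !length(pos)) return(empty_contacts())
  res_of <- paste(a$chain_id, a$residue_number)
  # candidate residue pairs (one negative, one positive)
  neg_res <- unique(res_of[neg]); pos_res <- unique(res_of[pos])
  rp <- expand.grid(nr = neg_res, pr = pos_res, stringsAsFactors = FALSE)
  nf <- n_frames(traj)
  out <- list()
  for (k in seq_len(nrow(rp))) {
    ni <- neg[res_of[neg] == rp$nr[k]]
    pi_ <- pos[res_of[pos] == rp$pr[k]]
    mind <- numeric(nf); close_pair <- matrix(0L, nf, 2)
    for (f in seq_len(nf)) {
      co <- frame_coords(traj, f)
      dmat <- outer(seq_along(ni), seq_along(pi_),
                    Vectorize(function(i, j) sqrt(sum((co[ni[i], ] - co[pi_[j], ])^2))))
      w <- which(dmat == min(dmat), arr.ind = TRUE)[1, ]
      mind[f] <- min(dmat)
      close_pair[f, ] <- c(ni[w[1]], pi_[w[2]])
    }
    q <- mind <= cutoff
    if (!any(q)) next
    bf <- which(q)[which.min(mind[q])]
    out[[length(out) + 1]] <- data.frame(
      kind = "saltbridge",
      donor_residue = a$residue_number[close_pair[bf, 2]],   # cation side
      donor_atom = a$atom_name[close_pair[bf, 2]],
      acceptor_residue = a$residue_number[close_pair[bf, 1]],
      acceptor_atom = a$atom_name[close_pair[bf, 1]],
      distance = mean(mind[q]),
      angle = NA_real_,
      occupancy = mean(q),
      angle_checked = FALSE,
      stringsAsFactors = FALSE)
  }
  if (!length(out)) return(empty_contacts())
  out <- do.call(rbind, out)
  rownames(out) <- NULL
  out
}
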