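# Coulomb constant in kcal * Angstrom / (mol * e^2)
KCOUL <- 332.0636

#' Generalized-Born model options
#'
#' OBC-II-style effective radii with HCT pairwise descreening and the
#' canonical interpolated pair distance
#' \code{f_GB = sqrt(r^2 + Bi Bj exp(-r^2 / (4 Bi Bj)))}.  Salt enters
#' through Debye screening of the solvent dielectric term,
#' \code{kappa = sqrt(I_molar) / 3.047} per Angstrom at 298 K.
#'
#' @param epsilon_in solute dielectric (default 1)
#' @param epsilon_out solvent dielectric (default 78.5)
#' @param salt_M monovalent salt concentration in mol/L (default 0.15)
#' @param offset radius offset subtracted before descreening, Angstrom
#'   (default 0, so an isolated atom's effective radius equals its intrinsic
#'   radius exactly; set 0.09 for the literature OBC offset)
#' @param alpha,beta,gamma OBC-II rescaling coefficients
#' @return list of class \code{gb_options}
#' @export
gb_options <- function(epsilon_in = 1, epsilon_out = 78.5, salt_M = 0.15,
                       offset = 0, alpha = 1, beta = 0.8, gamma = 4.85) {
  stopifnot(epsilon_in > 0, epsilon_out > 0, salt_M >= 0, offset >= 0)
  structure(list(epsilon_in = epsilon_in, epsilon_out = epsilon_out,
                 salt_M = salt_M, kappa = sqrt(salt_M) / 3.047,
                 offset = offset, alpha = alpha, beta = beta, gamma = gamma),
            class = "gb_options")
}

#' Built-in per-atom parameter table
#'
#' A small self-consistent set (charge, Lennard-Jones Rmin/2 and epsilon,
#' intrinsic GB radius, HCT descreening scale) covering backbone atoms and
#' the polar/charged side-chain atoms the synthetic fixtures use.  Wildcard
#' residue "*" rows match any residue lacking a specific entry.
#'
#' @return data.frame with columns \code{residue_name}, \code{atom_name},
#'   \code{charge}, \code{lj_rmin_half}, \code{lj_epsilon}, \code{gb_radius},
#'   \code{gb_scale}
#' @export
default_atom_params <- function() {
  read_atom_params(system.file("extdata", "default_atom_params.csv",
                               package = "helixnet", mustWork = TRUE))
}

#' Read a per-atom parameter CSV
#'
#' @param path CSV with columns \code{residue_name}, \code{atom_name},
#'   \code{charge}, \code{lj_rmin_half}, \code{lj_epsilon}, \code{gb_radius},
#'   \code{gb_scale}
#' @return validated data.frame
#' @export
read_atom_params <- function(path) {
  if (!file.exists(path)) stop("parameter file not found: ", path)
  p <- utils::read.csv(path, stringsAsFactors = FALSE)
  req <- c("residue_name", "atom_name", "charge", "lj_rmin_half",
           "lj_epsilon", "gb_radius", "gb_scale")
  miss <- setdiff(req, names(p))
  if (length(miss)) stop("parameter CSV missing columns: ",
                         paste(miss, collapse = ", "))
  if (any(p$lj_epsilon < 0)) stop("lj_epsilon must be >= 0")
  if (any(p$gb_radius <= 0)) stop("gb_radius must be > 0")
  p
}

#' Match parameters to every atom of a structure
#'
#' Exact (residue_name, atom_name) rows take precedence over wildcard
#' ("*", atom_name) rows; atoms without either are an error.
#'
#' @param x \code{helix_structure}
#' @param params parameter table (see \code{\link{read_atom_params}})
#' @return data.frame with one parameter row per atom, in atom order
#' @export
match_atom_params <- function(x, params) {
  a <- x$atoms
  key_exact <- paste(a$residue_name, a$atom_name)
  i <- match(key_exact, paste(params$residue_name, params$atom_name))
  wild <- is.na(i)
  i[wild] <- match(paste("*", a$atom_name[wild]),
                   paste(params$residue_name, params$atom_name))
  if (anyNA(i)) {
    bad <- unique(key_exact[is.na(i)])
    stop("no parameters for atom(s): ", paste(utils::head(bad, 8), collapse = "; "))
  }
  out <- params[i, c("charge", "lj_rmin_half", "lj_epsilon", "gb_radius", "gb_scale")]
  rownames(out) <- NULL
  out
}

# all-pairs Euclidean distance matrix (Angstrom), diag 0
dist_matrix <- function(coords) {
  d <- as.matrix(stats::dist(coords))
  dimnames(d) <- NULL
  d
}

#' Effective Born radii by pairwise descreening (OBC-II)
#'
#' Hawkins-Cramer-Truhlar pairwise descreening integrals summed over all
#' neighbours, then the OBC tanh rescaling
#' \code{1/B = 1/rho - tanh(a P - b P^2 + g P^3) / R} with
#' \code{P = rho * sum(I)}.  With the default zero radius offset an isolated
#' atom's effective radius equals its intrinsic radius.
#'
#' @param x \code{helix_structure}
#' @param params per-atom parameter rows (\code{\link{match_atom_params}}) or
#'   a parameter table to be matched
#' @param options \code{\link{gb_options}}
#' @return numeric vector of effective radii, Angstrom
#' @export
effective_born_radii <- function(x, params = default_atom_params(),
                                 options = gb_options()) {
  ap <- if (all(c("charge", "gb_radius") %in% names(params)) &&
            nrow(params) == n_atoms(x) &&
            !("residue_name" %in% names(params))) params
        else match_atom_params(x, params)
  n <- n_atoms(x)
  rho <- ap$gb_radius - options$offset
  if (any(rho <= 0)) stop("radius offset leaves a non-positive descreened radius")
  if (n == 1) {
    psi <- 0
  } else {
    r <- dist_matrix(x$coords)
    s <- matrix(ap$gb_scale * rho, n, n, byrow = TRUE)   # neighbour j scaled radius
    rho_i <- matrix(rho, n, n)                           # own descreened radius
    U <- r + s
    L <- pmax(rho_i, abs(r - s))
    active <- U > rho_i
    diag(active) <- FALSE
    I <- matrix(0, n, n)
    idx <- which(active)
    rr <- r[idx]; ss <- s[idx]; LL <- L[idx]; UU <- U[idx]; pp <- rho_i[idx]
    term <- 0.5 * (1 / LL - 1 / UU +
                   0.25 * (rr - ss^2 / rr) * (1 / UU^2 - 1 / LL^2) +
                   0.5 * log(LL / UU) / rr)
    engulf <- ss > (rr + pp)                     # atom i inside neighbour sphere
    term[engulf] <- term[engulf] + (1 / pp[engulf] - 1 / LL[engulf])
    I[idx] <- term
    psi <- rho * rowSums(I)
  }
  arg <- options$alpha * psi - options$beta * psi^2 + options$gamma * psi^3
  1 / (1 / rho - tanh(arg) / ap$gb_radius)
}

# GB screening prefactor tau(f): 1/eps_in - exp(-kappa f)/eps_out
gb_tau <- function(f, options) {
  1 / options$epsilon_in - exp(-options$kappa * f) / options$epsilon_out
}

#' Residue-pairwise interaction-energy decomposition
#'
#' For every residue pair (I, J), sums Coulomb, Lennard-Jones and the
#' pairwise generalized-Born polar cross term over all atom pairs (i in I,
#' j in J):
#' \deqn{E(I,J) = \sum_{i,j} k q_i q_j / (\epsilon_{in} r_{ij}) + LJ(r_{ij})
#'   - k \tau(f_{ij}) q_i q_j / f_{ij}}
#' with \code{f = sqrt(r^2 + Bi Bj exp(-r^2/(4 Bi Bj)))} and
#' \code{tau(f) = 1/eps_in - exp(-kappa f)/eps_out}.  Residue self-terms
#' (intra-residue atom pairs plus atomic Born self energies) are reported
#' separately in \code{$self}, never mixed into off-diagonal entries.
#'
#' @param x \code{helix_structure}
#' @param params parameter table or pre-matched per-atom rows
#' @param radii effective Born radii (computed if NULL)
#' @param options \code{\link{gb_options}}
#' @return object of class \code{pairwise_energy}: residue table, symmetric
#'   component matrices \code{coulomb}, \code{vdw}, \code{gb}, \code{total}
#'   (kcal/mol, zero diagonal), per-residue \code{self} table, logical
#'   \code{mask} (TRUE = excluded; initially only the diagonal), \code{meta}
#' @export
pairwise_interaction_energy <- function(x, params = default_atom_params(),
                                        radii = NULL, options = gb_options()) {
  ap <- if (all(c("charge", "gb_radius") %in% names(params)) &&
            nrow(params) == n_atoms(x) &&
            !("residue_name" %in% names(params))) params
        else match_atom_params(x, params)
  if (is.null(radii)) radii <- effective_born_radii(x, ap, options)
  n <- n_atoms(x)
  r <- dist_matrix(x$coords)
  off <- r[upper.tri(r)]
  if (any(off < 0.1))
    stop("overlapping atoms (distance < 0.1 A); check the input geometry")
  q <- ap$charge
  qq <- outer(q, q)
  # Coulomb
  coul <- KCOUL * qq / (options$epsilon_in * r)
  diag(coul) <- 0
  # Lennard-Jones (Rmin/2 + Rmin/2 combination, geometric epsilon)
  rmin <- outer(ap$lj_rmin_half, ap$lj_rmin_half, `+`)
  epsm <- sqrt(outer(ap$lj_epsilon, ap$lj_epsilon))
  sr6 <- (rmin / ifelse(r > 0, r, 1))^6
  vdw <- epsm * (sr6^2 - 2 * sr6)
  diag(vdw) <- 0
  # GB polar cross term
  bb <- outer(radii, radii)
  f <- sqrt(r^2 + bb * exp(-r^2 / (4 * bb)))
  gb <- -KCOUL * gb_tau(f, options) * qq / f
  gb_atom_self <- -0.5 * KCOUL * gb_tau(radii, options) * q^2 / radii
  diag(gb) <- 0
  # aggregate atoms -> residues
  at <- x$atoms
  res_key <- paste(at$chain_id, at$residue_number)
  resf <- factor(res_key, levels = unique(res_key))
  agg <- function(m) {
    g <- rowsum(m, resf, reorder = FALSE)
    g <- t(rowsum(t(g), resf, reorder = FALSE))
    dimnames(g) <- NULL
    g
  }
  coul_r <- agg(coul); vdw_r <- agg(vdw); gb_r <- agg(gb)
  self <- data.frame(coulomb = diag(coul_r) / 2, vdw = diag(vdw_r) / 2,
                     gb = diag(gb_r) / 2 +
                          as.numeric(rowsum(gb_atom_self, resf, reorder = FALSE)))
  self$total <- self$coulomb + self$vdw + self$gb
  rownames(self) <- NULL
  diag(coul_r) <- 0; diag(vdw_r) <- 0; diag(gb_r) <- 0
  residues <- residue_table(x)
  nres <- nrow(residues)
  mask <- matrix(FALSE, nres, nres); diag(mask) <- TRUE
  structure(list(residues = residues,
                 coulomb = coul_r, vdw = vdw_r, gb = gb_r,
                 total = coul_r + vdw_r + gb_r,
                 self = self, mask = mask,
                 meta = list(frames_averaged = 1L, replicate_id = NA,
                             exclusion_window = NA_integer_,
                             gb = unclass(options),
                             note = "nonpolar (SASA) term omitted: not pairwise-decomposable")),
            class = "pairwise_energy")
}

#' @export
print.pairwise_energy <- function(x, ...) {
  cat(sprintf("<pairwise_energy> %d residues; %d unmasked pairs; window=%s\n",
              nrow(x$residues), sum(!x$mask[upper.tri(x$mask)]),
              x$meta$exclusion_window))
  invisible(x)
}

#' Mask sequence-neighbour pairs
#'
#' Masks same-chain residue pairs with \code{|i - j| <= window} (and the
#' diagonal), removing the alpha-helical i..i+4 backbone hydrogen-bond ladder
#' and adjacent contacts from network analyses.  Masked entries keep their
#' values; only the mask changes, so masking is idempotent and reversible.
#' Pairs on different chains are never masked.
#'
#' @param mat \code{pairwise_energy} (or \code{avg_energy})
#' @param window non-negative integer sequence separation (default 4)
#' @return same class as \code{mat}, with the mask and
#'   \code{meta$exclusion_window} set
#' @export
apply_exclusion <- function(mat, window = 4) {
  window <- as.integer(window)
  if (is.na(window) || window < 0) stop("exclusion window must be >= 0")
  res <- mat$residues
  same_chain <- outer(res$chain_id, res$chain_id, `==`)
  sep <- abs(outer(res$residue_number, res$residue_number, `-`))
  mat$mask <- (same_chain & sep <= window)
  diag(mat$mask) <- TRUE
  mat$meta$exclusion_window <- window
  mat
}

#' Sum of energies over unmasked residue pairs
#' @param mat \code{pairwise_energy} or \code{avg_energy}
#' @param component matrix to sum ("total", "coulomb", "vdw", "gb", "mean")
#' @return scalar kcal/mol, each unordered pair counted once
#' @export
unmasked_total <- function(mat, component = if (inherits(mat, "avg_energy")) "mean" else "total") {
  m <- mat[[component]]
  sum(m[upper.tri(m) & !mat$mask])
}

#' Average replicate energy matrices
#'
#' Elementwise mean and standard error of the mean over replicates with
#' identical residue lists and masks.
#'
#' @param matrices list of \code{pairwise_energy} (or plain matrices sharing
#'   the first element's residue bookkeeping)
#' @return object of class \code{avg_energy}: \code{residues}, \code{mean},
#'   \code{sem}, \code{n}, \code{mask}, \code{meta}
#' @export
average_matrices <- function(matrices) {
  stopifnot(length(matrices) >= 1)
  first <- matrices[[1]]
  for (m in matrices[-1]) {
    if (!identical(m$residues$residue_number, first$residues$residue_number) ||
        !identical(m$residues$chain_id, first$residues$chain_id))
      stop("replicates have different residue lists")
    if (!identical(m$mask, first$mask))
      stop("replicates have different masks; apply the same exclusion first")
  }
  stack <- simplify2array(lapply(matrices, `[[`, "total"))
  mu <- apply(stack, c(1, 2), mean)
  n <- length(matrices)
  sem <- if (n > 1) apply(stack, c(1, 2), stats::sd) / sqrt(n)
         else matrix(0, nrow(mu), ncol(mu))
  structure(list(residues = first$residues, mean = mu, sem = sem, n = n,
                 mask = first$mask,
                 meta = list(exclusion_window = first$meta$exclusion_window)),
            class = "avg_energy")
}

#' @export
print.avg_energy <- function(x, ...) {
  cat(sprintf("<avg_energy> %d residues, n=%d replicates\n",
              nrow(x$residues), x$n))
  invisible(x)
}

res_label <- function(residues) {
  single <- length(unique(residues$chain_id)) == 1
  if (single) as.character(residues$residue_number)
  else paste0(residues$chain_id, ":", residues$residue_number)
}

parse_res_label <- function(lab) {
  lab <- as.character(lab)
  has_chain <- grepl(":", lab, fixed = TRUE)
  chain <- ifelse(has_chain, sub(":.*$", "", lab), "A")
  resno <- as.integer(ifelse(has_chain, sub("^.*:", "", lab), lab))
  if (anyNA(resno)) stop("unparseable residue label(s): ",
                         paste(utils::head(unique(lab[is.na(resno)]), 5), collapse = ", "))
  data.frame(chain_id = chain, residue_number = resno, stringsAsFactors = FALSE)
}

#' Export a pairwise matrix as a decomposition CSV
#'
#' Writes the common per-residue pairwise decomposition dialect: columns
#' \code{residue_i, residue_j, internal, vdw, electrostatic, polar_solv,
#' nonpolar_solv, total}, one row per unordered residue pair (diagonal
#' excluded).  \code{internal} and \code{nonpolar_solv} are zero here.
#'
#' @param mat \code{pairwise_energy}
#' @param path output CSV
#' @param include_masked write masked pairs too (default TRUE)
#' @return invisibly, the path
#' @export
export_decomposition <- function(mat, path, include_masked = TRUE) {
  lab <- res_label(mat$residues)
  ut <- which(upper.tri(mat$total), arr.ind = TRUE)
  if (!include_masked) ut <- ut[!mat$mask[upper.tri(mat$mask)], , drop = FALSE]
  df <- data.frame(residue_i = lab[ut[, 1]], residue_j = lab[ut[, 2]],
                   internal = 0,
                   vdw = mat$vdw[ut],
                   electrostatic = mat$coulomb[ut],
                   polar_solv = mat$gb[ut],
                   nonpolar_solv = 0,
                   total = mat$total[ut])
  utils::write.csv(df, path, row.names = FALSE)
  invisible(path)
}

#' Import an external pairwise decomposition CSV
#'
#' Reads the dialect written by \code{\link{export_decomposition}} (and by
#' common MM-GBSA decomposition tools): required columns
#' \code{residue_i, residue_j, internal, vdw, electrostatic, polar_solv,
#' nonpolar_solv, total}.  If both (i,j) and (j,i) rows are present the
#' matrix is symmetrized by averaging; discrepancies beyond \code{tol} raise
#' a warning with the maximum discrepancy.
#'
#' @param path CSV path
#' @param tol symmetry tolerance in kcal/mol (default 1e-6)
#' @return \code{pairwise_energy} (self-terms zero, mask = diagonal)
#' @export
import_decomposition <- function(path, tol = 1e-6) {
  if (!file.exists(path)) stop("decomposition file not found: ", path)
  df <- utils::read.csv(path, stringsAsFactors = FALSE)
  req <- c("residue_i", "residue_j", "internal", "vdw", "electrostatic",
           "polar_solv", "nonpolar_solv", "total")
  miss <- setdiff(req, names(df))
  if (length(miss)) stop("decomposition CSV missing columns: ",
                         paste(miss, collapse = ", "))
  ri <- parse_res_label(df$residue_i); rj <- parse_res_label(df$residue_j)
  all_res <- unique(rbind(ri, rj))
  all_res <- all_res[order(all_res$chain_id, all_res$residue_number), ]
  rownames(all_res) <- NULL
  all_res$residue_name <- "UNK"
  key <- function(d) paste(d$chain_id, d$residue_number)
  ii <- match(key(ri), key(all_res)); jj <- match(key(rj), key(all_res))
  nres <- nrow(all_res)
  build <- function(v) {
    m <- matrix(0, nres, nres); cnt <- matrix(0L, nres, nres)
    lo <- matrix(NA_real_, nres, nres); hi <- lo
    for (k in seq_along(v)) {
      a <- min(ii[k], jj[k]); b <- max(ii[k], jj[k])
      m[a, b] <- m[a, b] + v[k]; cnt[a, b] <- cnt[a, b] + 1L
      lo[a, b] <- min(lo[a, b], v[k], na.rm = TRUE)
      hi[a, b] <- max(hi[a, b], v[k], na.rm = TRUE)
    }
    got <- cnt > 0
    m[got] <- m[got] / cnt[got]
    disc <- suppressWarnings(max(hi - lo, na.rm = TRUE))
    m <- m + t(m); diag(m) <- 0
    list(m = m, max_disc = if (is.finite(disc)) disc else 0)
  }
  tot <- build(df$total); vdw <- build(df$vdw)
  ele <- build(df$electrostatic); pol <- build(df$polar_solv)
  if (tot$max_disc > tol)
    warning(sprintf("asymmetric duplicate pairs symmetrized by averaging; max discrepancy %.3g kcal/mol",
                    tot$max_disc))
  mask <- matrix(FALSE, nres, nres); diag(mask) <- TRUE
  self <- data.frame(coulomb = rep(0, nres), vdw = 0, gb = 0, total = 0)
  structure(list(residues = all_res[, c("chain_id", "residue_number", "residue_name")],
                 coulomb = ele$m, vdw = vdw$m, gb = pol$m, total = tot$m,
                 self = self, mask = mask,
                 meta = list(frames_averaged = NA_integer_, replicate_id = NA,
                             exclusion_window = NA_integer_, source = path,
                             max_symmetry_discrepancy = tot$max_disc)),
            class = "pairwise_energy")
}

#' Write a matrix in long form (res_i, res_j, components, masked flag)
#'
#' @param mat \code{pairwise_energy} or \code{avg_energy}
#' @param path output CSV
#' @return invisibly, the path
#' @export
write_energy_csv <- function(mat, path) {
  lab <- res_label(mat$residues)
  ut <- which(upper.tri(mat$mask), arr.ind = TRUE)
  if (inherits(mat, "avg_energy")) {
    df <- data.frame(res_i = lab[ut[, 1]], res_j = lab[ut[, 2]],
                     mean = mat$mean[ut], sem = mat$sem[ut],
                     masked = mat$mask[ut])
  } else {
    df <- data.frame(res_i = lab[ut[, 1]], res_j = lab[ut[, 2]],
                     coulomb = mat$coulomb[ut], vdw = mat$vdw[ut],
                     gb = mat$gb[ut], total = mat$total[ut],
                     masked = mat$mask[ut])
  }
  utils::write.csv(df, path, row.names = FALSE)
  invisible(path)
}
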