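# Per-residue structural descriptors from a predicted structure:
# pLDDT confidence, hydrogen-bond counts, salt-bridge presence and relative
# solvent accessibility. Geometry criteria are distance-only on heavy atoms
# (predicted models carry no hydrogens).

.backbone_names <- c("N", "CA", "C", "O", "OXT")

.coord_matrix <- function(struct, sel = TRUE) {
  as.matrix(struct[sel, c("x", "y", "z"), drop = FALSE])
}

.ca_matrix <- function(struct) {
  ca <- struct[struct$elety == "CA", , drop = FALSE]
  ca <- ca[order(ca$resno), , drop = FALSE]
  m <- .coord_matrix(ca)
  rownames(m) <- ca$resno
  m
}

#' Mean pLDDT of a structure
#'
#' Mean over residues of the per-residue confidence stored in the B-factor
#' column (read from the CA atom; Alphafold2 writes the same value on every
#' atom of a residue). Proteins with mean pLDDT below 70 are excluded from
#' structure-dependent analyses downstream.
#'
#' @param struct A \code{psd_structure}.
#' @return Mean pLDDT in [0, 100].
#' @export
mean_plddt <- function(struct) {
  ca <- struct[struct$elety == "CA", , drop = FALSE]
  all_res <- unique(struct$resno)
  if (length(all_res) == 0L) stop("empty structure")
  missing_ca <- setdiff(all_res, ca$resno)
  if (length(missing_ca) > 0L)
    warning("residue(s) without CA skipped in mean pLDDT: ",
            paste(missing_ca, collapse = ", "))
  if (nrow(ca) == 0L) stop("no CA atoms in structure")
  mean(ca$b)
}

#' Count hydrogen bonds involving one residue
#'
#' Counts donor/acceptor heavy-atom pairs (N or O atoms) between the residue
#' and any other residue with an inter-atom distance in [2.5, 3.2] Angstrom.
#' A pair is classified by which of the residue's own atoms participates:
#' backbone N/O/OXT gives a backbone bond, side-chain N/O a side-chain bond.
#' The classification is symmetric across residues: a side-chain-to-backbone
#' contact increments one residue's side-chain count and the partner's
#' backbone count. Intra-residue pairs are excluded. Glycine, with no
#' side-chain N/O, always has side-chain count 0.
#'
#' @param struct A \code{psd_structure}.
#' @param position Residue index (1-based).
#' @param range Distance window in Angstrom (default \code{c(2.5, 3.2)}).
#' @return Named integer vector \code{c(backbone = , sidechain = )}.
#' @export
count_hbonds <- function(struct, position, range = c(2.5, 3.2)) {
  polar <- struct[struct$element %in% c("N", "O"), , drop = FALSE]
  own <- polar[polar$resno == position, , drop = FALSE]
  other <- polar[polar$resno != position, , drop = FALSE]
  if (nrow(own) == 0L || nrow(other) == 0L)
    return(c(backbone = 0L, sidechain = 0L))
  d <- .pairwise_dist(.coord_matrix(own), .coord_matrix(other))
  inwin <- d >= range[1] & d <= range[2]
  is_bb <- own$elety %in% .backbone_names
  c(backbone = sum(inwin[is_bb, , drop = FALSE]),
    sidechain = sum(inwin[!is_bb, , drop = FALSE]))
}

.pairwise_dist <- function(a, b) {
  # dense Euclidean distances between rows of a and rows of b
  an <- rowSums(a^2); bn <- rowSums(b^2)
  d2 <- outer(an, bn, "+") - 2 * tcrossprod(a, b)
  sqrt(pmax(d2, 0))
}

#' Salt-bridge presence for a D/E residue
#'
#' TRUE iff any side-chain carboxylate oxygen of the residue (OD1/OD2 for D,
#' OE1/OE2 for E) lies strictly under \code{cutoff} Angstrom from a
#' side-chain nitrogen of a lysine (NZ) or arginine (NE/NH1/NH2). Residues
#' other than D/E never qualify (asparagine's amide cannot form the
#' electrostatic pairing).
#'
#' @param struct A \code{psd_structure}.
#' @param position Residue index.
#' @param cutoff Distance cutoff in Angstrom (default 4.0, exclusive).
#' @return Logical scalar.
#' @export
has_salt_bridge <- function(struct, position, cutoff = 4.0) {
  res <- struct[struct$resno == position, , drop = FALSE]
  if (nrow(res) == 0L) stop("no such residue: ", position)
  code <- res$resid[1]
  if (!code %in% c("D", "E")) return(FALSE)
  acid_names <- if (code == "D") c("OD1", "OD2") else c("OE1", "OE2")
  acid <- res[res$elety %in% acid_names, , drop = FALSE]
  if (nrow(acid) == 0L) return(FALSE)
  basic <- struct[(struct$resid == "K" & struct$elety == "NZ") |
                  (struct$resid == "R" &
                     struct$elety %in% c("NE", "NH1", "NH2")), , drop = FALSE]
  basic <- basic[basic$resno != position, , drop = FALSE]
  if (nrow(basic) == 0L) return(FALSE)
  d <- .pairwise_dist(.coord_matrix(acid), .coord_matrix(basic))
  any(d < cutoff)
}

# van der Waals radii (Angstrom) for heavy atoms
.vdw_radius <- c(C = 1.70, N = 1.55, O = 1.52, S = 1.80)

# Maximum accessible surface areas (Angstrom^2) per residue, theoretical
# values of Tien et al. (2013), used to normalize SASA to relative
# accessibility.
.max_asa <- c(
  A = 129, R = 274, N = 195, D = 193, C = 167, Q = 225, E = 223, G = 104,
  H = 224, I = 197, L = 201, K = 236, M = 224, F = 240, P = 159, S = 155,
  T = 172, W = 285, Y = 263, V = 174
)

# deterministic unit sphere points (golden-spiral lattice)
.sphere_points <- function(n) {
  i <- seq_len(n) - 0.5
  phi <- acos(1 - 2 * i / n)
  theta <- pi * (1 + sqrt(5)) * i
  cbind(sin(phi) * cos(theta), sin(phi) * sin(theta), cos(phi))
}

#' Solvent-accessible surface area per atom (Shrake-Rupley)
#'
#' Rolling-probe SASA on heavy atoms: each atom's accessible area is the
#' fraction of points on its probe-expanded sphere not buried inside any
#' neighbouring atom's expanded sphere, times the sphere area.
#'
#' @param struct A \code{psd_structure}.
#' @param probe Probe radius in Angstrom (default 1.4, water).
#' @param n_points Sphere test points per atom (default 240).
#' @return Numeric vector of per-atom SASA (Angstrom^2).
#' @export
atom_sasa <- function(struct, probe = 1.4, n_points = 240L) {
  xyz <- .coord_matrix(struct)
  r <- .vdw_radius[struct$element]
  r[is.na(r)] <- 1.70
  re <- r + probe
  n <- nrow(xyz)
  pts <- .sphere_points(n_points)
  out <- numeric(n)
  d <- .pairwise_dist(xyz, xyz)
  for (i in seq_len(n)) {
    nb <- which(d[i, ] < re[i] + re & seq_len(n) != i)
    if (length(nb) == 0L) {
      out[i] <- 4 * pi * re[i]^2
      next
    }
    sp <- sweep(pts * re[i], 2L, xyz[i, ], "+")
    buried <- rep(FALSE, n_points)
    for (j in nb) {
      dj2 <- (sp[, 1] - xyz[j, 1])^2 + (sp[, 2] - xyz[j, 2])^2 +
             (sp[, 3] - xyz[j, 3])^2
      buried <- buried | dj2 < re[j]^2
      if (all(buried)) break
    }
    out[i] <- 4 * pi * re[i]^2 * mean(!buried)
  }
  out
}

#' Relative solvent accessibility per residue
#'
#' Per-residue SASA (sum over the residue's heavy atoms) divided by the
#' residue type's maximum ASA (Tien et al. 2013 theoretical scale). Values
#' can slightly exceed 1 for very exposed residues. Residues with missing
#' side-chain heavy atoms are computed on the available atoms (a single
#' consolidated warning reports how many).
#'
#' @param struct A \code{psd_structure}.
#' @param probe Probe radius (default 1.4 Angstrom).
#' @param n_points Sphere points per atom (default 240).
#' @return Named numeric vector of relative accessibility, names = residue
#'   indices.
#' @export
relative_solvent_accessibility <- function(struct, probe = 1.4,
                                           n_points = 240L) {
  sasa <- atom_sasa(struct, probe, n_points)
  per_res <- tapply(sasa, struct$resno, sum)
  codes <- vapply(split(struct$resid, struct$resno), `[[`, "", 1L)
  expected <- .sidechain_heavy_count[codes] + 4L
  observed <- as.integer(table(struct$resno)[names(per_res)])
  short <- sum(observed < expected, na.rm = TRUE)
  if (short > 0L)
    warning(short, " residue(s) missing side-chain heavy atoms; ",
            "accessibility computed on available atoms")
  rsa <- as.numeric(per_res) / .max_asa[codes]
  names(rsa) <- names(per_res)
  rsa
}

# side-chain heavy-atom counts of full residues (for completeness warnings)
.sidechain_heavy_count <- c(
  A = 1L, R = 7L, N = 4L, D = 4L, C = 2L, Q = 5L, E = 5L, G = 0L, H = 6L,
  I = 4L, L = 4L, K = 5L, M = 4L, F = 7L, P = 3L, S = 2L, T = 3L, W = 10L,
  Y = 8L, V = 3L
)
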