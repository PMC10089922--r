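# Accessible-volume (AV/AV3) and accessible-contact-volume (ACV) dye-cloud
# computation on PDB structures, and model-versus-experiment distance
# comparison.

.vdw_table <- c(C = 1.70, N = 1.55, O = 1.52, S = 1.80, P = 1.80,
                H = 1.20, FE = 1.40, ZN = 1.39, MG = 1.73)

#' Parse a PDB structure
#'
#' Reads heavy atoms (coordinates, element, residue, chain) and assigns van
#' der Waals radii by element. Multi-model files default to the first model.
#'
#' @param path PDB file.
#' @param chain optional chain selection.
#' @param keep_h keep hydrogens (default drops them).
#' @return a `pdb_structure` data frame with x, y, z, element, resno,
#'   chain, atom name and `vdw` radius.
#' @export
parse_structure <- function(path, chain = NULL, keep_h = FALSE) {
  pdb <- bio3d::read.pdb(path, multi = FALSE, verbose = FALSE)
  a <- pdb$atom[pdb$atom$type %in% c("ATOM", "HETATM"), , drop = FALSE]
  if (!is.null(chain)) a <- a[a$chain %in% chain, , drop = FALSE]
  el <- toupper(trimws(a$elesy))
  el[is.na(el) | el == ""] <- substr(trimws(a$elety[is.na(el) | el == ""]),
                                     1, 1)
  if (!keep_h) {
    keep <- el != "H"
    a <- a[keep, , drop = FALSE]; el <- el[keep]
  }
  if (!nrow(a)) stop("no atoms parsed from ", path)
  out <- data.frame(x = a$x, y = a$y, z = a$z, element = el,
                    atom = trimws(a$elety), resno = a$resno,
                    resid = a$resid, chain = a$chain,
                    vdw = unname(ifelse(el %in% names(.vdw_table),
                                        .vdw_table[el], 1.7)))
  class(out) <- c("pdb_structure", "data.frame")
  out
}

#' Locate a dye attachment atom
#'
#' @param structure a [parse_structure()] result.
#' @param resno residue sequence number.
#' @param atom atom name (default `"CB"`, the labelling-site convention).
#' @param chain optional chain.
#' @export
find_attachment <- function(structure, resno, atom = "CB", chain = NULL) {
  sel <- structure$resno == resno & structure$atom == atom
  if (!is.null(chain)) sel <- sel & structure$chain == chain
  i <- which(sel)
  if (!length(i))
    stop("attachment residue ", resno, " (atom ", atom,
         ") not found in structure")
  i[1]
}

#' Coarse-grained dye parameters
#'
#' The five-parameter dye model: linker length and width, and up to three
#' radii defining the fluorophore volume. Values are user inputs; the
#' defaults are generic literature-style values for cyanine/rhodamine-class
#' dyes, not measurement-specific calibrations.
#'
#' @param linker_length_A,linker_width_A linker geometry.
#' @param dye_radii_A one (AV1) or three (AV3) radii, nonincreasing.
#' @param grid_spacing_A AV grid spacing (<= 1 recommended).
#' @export
dye_parameters <- function(linker_length_A = 20, linker_width_A = 4.5,
                           dye_radii_A = c(5, 4.5, 1.5),
                           grid_spacing_A = 0.9) {
  stopifnot(linker_length_A > 0, linker_width_A > 0,
            all(dye_radii_A > 0), grid_spacing_A > 0)
  if (is.unsorted(rev(dye_radii_A)))
    stop("dye radii must be nonincreasing (R1 >= R2 >= R3)")
  structure(list(L = linker_length_A, w = linker_width_A,
                 radii = dye_radii_A, spacing = grid_spacing_A),
            class = "dye_parameters")
}

#' Accessible-volume dye cloud
#'
#' Deterministic grid computation of all sterically allowed dye positions
#' around an attachment atom: a cubic grid of the linker length is
#' flood-filled from the attachment point, path clearance must exceed half
#' the linker width, the geodesic (around-obstacle) distance must not
#' exceed the linker length, and the dye position clearance must exceed the
#' dye radius plus the local van der Waals radius. `AV3` unites the volumes
#' of the three dye radii with equal weight.
#'
#' @param structure a [parse_structure()] result.
#' @param attach_idx row index of the attachment atom (see
#'   [find_attachment()]).
#' @param params a [dye_parameters()].
#' @param model `"AV1"` (first radius only) or `"AV3"`.
#' @return an `av_cloud`: `points` (n x 3), normalised `weights`, mean dye
#'   position, attachment coordinates, grid spacing.
#' @export
compute_av <- function(structure, attach_idx, params = dye_parameters(),
                       model = c("AV3", "AV1")) {
  model <- match.arg(model)
  if (params$spacing > 1)
    stop("grid spacing must be <= 1 Angstrom")
  att <- as.numeric(structure[attach_idx, c("x", "y", "z")])
  g <- params$spacing
  L <- params$L
  half <- ceiling(L / g)
  ax <- seq(-half, half) * g
  nd <- length(ax)
  pts <- as.matrix(expand.grid(x = ax + att[1], y = ax + att[2],
                               z = ax + att[3]))
  # obstacle atoms near the grid (exclude the attachment atom itself)
  atoms <- structure[-attach_idx, , drop = FALSE]
  d_att <- sqrt((atoms$x - att[1])^2 + (atoms$y - att[2])^2 +
                  (atoms$z - att[3])^2)
  near <- atoms[d_att < L + max(atoms$vdw) + max(params$radii) + 2 * g, ,
                drop = FALSE]
  # clearance: min over atoms of (distance - vdw)
  clear <- rep(Inf, nrow(pts))
  if (nrow(near)) {
    for (i in seq_len(nrow(near))) {
      d <- sqrt((pts[, 1] - near$x[i])^2 + (pts[, 2] - near$y[i])^2 +
                  (pts[, 3] - near$z[i])^2) - near$vdw[i]
      clear <- pmin(clear, d)
    }
  }
  radii <- if (model == "AV1") params$radii[1] else params$radii
  path_ok <- clear >= params$w / 2
  rad_att <- sqrt(rowSums(sweep(pts, 2, att)^2))
  cand <- path_ok & rad_att <= L
  if (!any(cand) || min(rad_att[cand]) > max(2 * g, params$w))
    stop("attachment is fully buried: empty dye cloud")
  # geodesic distance from the attachment on the path-allowed grid,
  # seeded at the allowed point nearest the attachment atom
  src <- which(cand)[which.min(rad_att[cand])]
  geo <- .grid_geodesic(cand, nd, g, src)
  reach <- is.finite(geo) & geo <= L
  counts <- numeric(nrow(pts))
  for (r in radii) counts <- counts + (reach & clear >= r)
  keep <- counts > 0
  if (!any(keep)) stop("empty dye cloud for all radii")
  w <- counts[keep] / sum(counts[keep])
  cloud <- structure(list(points = pts[keep, , drop = FALSE], weights = w,
                          attachment = att, spacing = g, model = model,
                          radii = radii,
                          surface_clearance = clear[keep],
                          contact_fraction = NA_real_, flavor = "AV"),
                     class = "av_cloud")
  cloud$mean_position <- colSums(cloud$points * cloud$weights)
  cloud
}

# Dijkstra geodesic distances on the free subset of a cubic grid
.grid_geodesic <- function(free, nd, spacing, source_idx) {
  idx_free <- which(free)
  if (!free[source_idx]) {
    # snap source to nearest free point
    source_idx <- idx_free[1]
  }
  nfree <- length(idx_free)
  pos <- match(seq_len(nd^3), idx_free)   # grid index -> free node id
  # neighbour offsets (13 unique half-space directions of the 26-neighbourhood)
  off <- as.matrix(expand.grid(dx = -1:1, dy = -1:1, dz = -1:1))
  off <- off[off[, 1] > 0 | (off[, 1] == 0 & off[, 2] > 0) |
               (off[, 1] == 0 & off[, 2] == 0 & off[, 3] > 0), ,
             drop = FALSE]
  ii <- ((idx_free - 1) %% nd)
  jj <- ((idx_free - 1) %/% nd) %% nd
  kk <- (idx_free - 1) %/% (nd * nd)
  el <- NULL; wt <- NULL
  for (o in seq_len(nrow(off))) {
    i2 <- ii + off[o, 1]; j2 <- jj + off[o, 2]; k2 <- kk + off[o, 3]
    ok <- i2 >= 0 & i2 < nd & j2 >= 0 & j2 < nd & k2 >= 0 & k2 < nd
    tgt <- i2[ok] + nd * j2[ok] + nd * nd * k2[ok] + 1
    tfree <- !is.na(pos[tgt])
    src_node <- pos[idx_free[ok]][tfree]
    tgt_node <- pos[tgt][tfree]
    if (!length(src_node)) next
    el <- rbind(el, cbind(src_node, tgt_node))
    wt <- c(wt, rep(sqrt(sum(off[o, ]^2)) * spacing, length(src_node)))
  }
  geo_free <- rep(Inf, nfree)
  if (!is.null(el)) {
    gr <- igraph::graph_from_edgelist(el, directed = FALSE)
    gr <- igraph::set_edge_attr(gr, "weight", value = wt)
    if (igraph::vcount(gr) < nfree)
      gr <- igraph::add_vertices(gr, nfree - igraph::vcount(gr))
    geo_free <- as.numeric(igraph::distances(
      gr, v = pos[source_idx], weights = igraph::E(gr)$weight))
  } else {
    geo_free[pos[source_idx]] <- 0
  }
  out <- rep(Inf, nd^3)
  out[idx_free] <- geo_free
  out
}

#' Accessible contact volume
#'
#' Reweights an AV cloud so that the thin surface layer (points whose dye
#' surface lies within `shell_A` of the protein surface) carries exactly
#' `contact_fraction` of the total weight, emulating dyes that stick to the
#' biomolecule; weights stay uniform (up to the AV3 multiplicity) within
#' the contact and free sets. `contact_fraction = 0` returns the AV
#' unchanged.
#'
#' @param cloud an [compute_av()] result.
#' @param shell_A contact-layer thickness (default 3).
#' @param contact_fraction fraction of dye weight in the contact layer,
#'   in [0, 1] (e.g. from residual anisotropy via
#'   [contact_fraction_from_anisotropy()]).
#' @return reweighted `av_cloud` with `flavor = "ACV"`.
#' @export
compute_acv <- function(cloud, shell_A = 3, contact_fraction) {
  stopifnot(inherits(cloud, "av_cloud"),
            contact_fraction >= 0, contact_fraction <= 1)
  if (contact_fraction == 0) return(cloud)
  rd <- mean(cloud$radii)
  contact <- cloud$surface_clearance - rd <= shell_A
  if (!any(contact))
    stop("no AV points in the contact shell; cannot assign contact weight")
  w <- cloud$weights
  wc <- sum(w[contact]); wf <- sum(w[!contact])
  if (wf == 0) {
    w <- w / sum(w)
  } else {
    w[contact] <- w[contact] / wc * contact_fraction
    w[!contact] <- w[!contact] / wf * (1 - contact_fraction)
  }
  cloud$weights <- w
  cloud$mean_position <- colSums(cloud$points * w)
  cloud$contact_fraction <- contact_fraction
  cloud$flavor <- "ACV"
  cloud
}

#' Contact fraction from residual anisotropy
#'
#' Monotone mapping of a dye's residual anisotropy to the trapped (sticking)
#' fraction: f = r_inf / r0.
#'
#' @param r_inf residual anisotropy; `r0` fundamental anisotropy.
#' @export
contact_fraction_from_anisotropy <- function(r_inf, r0 = 0.38) {
  if (any(r_inf < 0) || any(r_inf > r0))
    stop("r_inf must lie in [0, r0]")
  r_inf / r0
}

#' Model distances between two dye clouds
#'
#' Computes the FRET-averaged model efficiency
#' <E> = sum_ij w_i w_j / (1 + (R_ij/R0)^6), the FRET-efficiency-averaged
#' distance R<E> (Forster inversion of <E>), the mean interdye distance
#' <R_DA> and the mean-position distance R_mp. Pair sums are exact up to
#' `max_pairs` pairs, beyond which stratified subsampling with a reported
#' standard error is used.
#'
#' @param cloud_d,cloud_a donor/acceptor `av_cloud`s.
#' @param r0_A Forster radius.
#' @param max_pairs exact-summation limit.
#' @param n_strata subsampling replicates for the standard error.
#' @return a `model_distance` list with `R_mp`, `R_mean`, `R_E`, `E_mean`,
#'   and `se_A` (0 for exact sums).
#' @export
model_distances <- function(cloud_d, cloud_a, r0_A, max_pairs = 4e6,
                            n_strata = 10) {
  nd <- nrow(cloud_d$points); na <- nrow(cloud_a$points)
  pair_sums <- function(pd, wd, pa, wa) {
    sE <- 0; sR <- 0
    chunk <- max(1, floor(2e6 / max(1, nrow(pa))))
    for (i0 in seq(1, nrow(pd), by = chunk)) {
      i1 <- min(i0 + chunk - 1, nrow(pd))
      d2 <- outer(rowSums(pd[i0:i1, , drop = FALSE]^2), rowSums(pa^2),
                  "+") - 2 * pd[i0:i1, , drop = FALSE] %*% t(pa)
      R <- sqrt(pmax(d2, 0))
      W <- outer(wd[i0:i1], wa)
      sE <- sE + sum(W / (1 + (R / r0_A)^6))
      sR <- sR + sum(W * R)
    }
    c(E = sE, R = sR)
  }
  if (as.double(nd) * na <= max_pairs) {
    s <- pair_sums(cloud_d$points, cloud_d$weights,
                   cloud_a$points, cloud_a$weights)
    E_mean <- s[["E"]]; R_mean <- s[["R"]]; se <- 0
  } else {
    m <- floor(sqrt(max_pairs / n_strata))
    Es <- Rs <- numeric(n_strata)
    for (k in seq_len(n_strata)) {
      id <- sample.int(nd, m, replace = TRUE, prob = cloud_d$weights)
      ia <- sample.int(na, m, replace = TRUE, prob = cloud_a$weights)
      s <- pair_sums(cloud_d$points[id, , drop = FALSE],
                     rep(1 / m, m),
                     cloud_a$points[ia, , drop = FALSE], rep(1 / m, m))
      Es[k] <- s[["E"]]; Rs[k] <- s[["R"]]
    }
    E_mean <- mean(Es); R_mean <- mean(Rs)
    se <- sd(Rs) / sqrt(n_strata)
  }
  R_E <- r0_A * (1 / E_mean - 1)^(1 / 6)
  structure(list(
    R_mp = sqrt(sum((cloud_d$mean_position - cloud_a$mean_position)^2)),
    R_mean = R_mean, R_E = R_E, E_mean = E_mean, se_A = se, r0_A = r0_A),
    class = "model_distance")
}

#' Compare model and experimental distances
#'
#' Signed deviations, root-mean-square deviation per model flavour and the
#' number of pairs within a tolerance band.
#'
#' @param R_exp experimental FRET-averaged distances (Angstrom).
#' @param R_av,R_acv model distances (AV and optionally ACV).
#' @param sigma_exp experimental uncertainties (optional).
#' @param band tolerance band (default +/- 3 Angstrom).
#' @return list with the deviation table and per-flavour RMSD.
#' @export
compare_model_experiment <- function(R_exp, R_av, R_acv = NULL,
                                     sigma_exp = NULL, band = 3) {
  stopifnot(length(R_exp) >= 1, length(R_av) == length(R_exp))
  tab <- data.frame(R_exp = R_exp, R_av = R_av,
                    dev_av = R_av - R_exp)
  rmsd <- c(AV = sqrt(mean(tab$dev_av^2)))
  within <- c(AV = sum(abs(tab$dev_av) <= band))
  if (!is.null(R_acv)) {
    tab$R_acv <- R_acv
    tab$dev_acv <- R_acv - R_exp
    rmsd <- c(rmsd, ACV = sqrt(mean(tab$dev_acv^2)))
    within <- c(within, ACV = sum(abs(tab$dev_acv) <= band))
  }
  if (!is.null(sigma_exp)) tab$sigma_exp <- sigma_exp
  list(table = tab, rmsd = rmsd, n_within_band = within, band = band)
}
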