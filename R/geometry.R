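## Structural operators: glycosidic torsion, syn/anti classification,
## inter-base stacking overlap area, conformer census over ensembles.

## ordered ring-atom cycles per base type; purines carry the fused
## five-membered ring as a second cycle sharing the C4-C5 edge
ring_atom_cycles <- list(
  A = list(six = c("C4", "C5", "C6", "N1", "C2", "N3"),
           five = c("N9", "C4", "C5", "N7", "C8")),
  G = list(six = c("C4", "C5", "C6", "N1", "C2", "N3"),
           five = c("N9", "C4", "C5", "N7", "C8")),
  C = list(six = c("N1", "C2", "N3", "C4", "C5", "C6")),
  T = list(six = c("N1", "C2", "N3", "C4", "C5", "C6"))
)

chi_atom_names <- function(base_type) {
  if (base_type %in% c("A", "G")) c("O4'", "C1'", "N9", "C4")
  else c("O4'", "C1'", "N1", "C2")
}

#' Construct a nucleotide structure
#'
#' @param residue_id Identifier (number or string).
#' @param base_type One of `"A"`, `"G"`, `"C"`, `"T"`.
#' @param atoms Named list of length-3 coordinates (Angstrom), or a
#'   3-column matrix with atom-name rownames. Must contain the four
#'   glycosidic-torsion atoms and all base ring heavy atoms.
#' @return An object of class `"nucleotide_structure"`.
#' @export
nucleotide_structure <- function(residue_id, base_type, atoms) {
  base_type <- match.arg(base_type, c("A", "G", "C", "T"))
  if (is.list(atoms)) atoms <- do.call(rbind, atoms)
  if (is.null(rownames(atoms)) || ncol(atoms) != 3)
    stop("atoms must be a named 3-column coordinate set")
  required <- unique(c(chi_atom_names(base_type),
                       unlist(ring_atom_cycles[[base_type]])))
  missing <- setdiff(required, rownames(atoms))
  if (length(missing))
    stop("missing atom(s) for ", base_type, ": ",
         paste(missing, collapse = ", "))
  structure(list(residue_id = residue_id, base_type = base_type,
                 atoms = atoms),
            class = "nucleotide_structure")
}

#' @export
print.nucleotide_structure <- function(x, ...) {
  cat(sprintf("<nucleotide %s (%s), %d atoms>\n", x$residue_id, x$base_type,
              nrow(x$atoms)))
  invisible(x)
}

cross3 <- function(a, b) {
  c(a[2] * b[3] - a[3] * b[2],
    a[3] * b[1] - a[1] * b[3],
    a[1] * b[2] - a[2] * b[1])
}

#' Signed dihedral angle of four points
#'
#' IUPAC sign convention; result in (-180, 180] degrees.
#'
#' @param p1,p2,p3,p4 Length-3 coordinates.
#' @return Angle in degrees.
#' @export
dihedral_angle <- function(p1, p2, p3, p4) {
  b1 <- p2 - p1; b2 <- p3 - p2; b3 <- p4 - p3
  n1 <- cross3(b1, b2); n2 <- cross3(b2, b3)
  m1 <- cross3(n1, b2 / sqrt(sum(b2^2)))
  ang <- -atan2(sum(m1 * n2), sum(n1 * n2)) * 180 / pi
  if (ang <= -180) ang <- ang + 360
  ang
}

#' Glycosidic torsion angle chi
#'
#' O4'-C1'-N9-C4 for purines, O4'-C1'-N1-C2 for pyrimidines; signed
#' dihedral in (-180, 180], invariant under rigid-body motion.
#'
#' @param nuc A `nucleotide_structure`.
#' @return chi in degrees.
#' @export
chi_torsion <- function(nuc) {
  stopifnot(inherits(nuc, "nucleotide_structure"))
  nm <- chi_atom_names(nuc$base_type)
  missing <- setdiff(nm, rownames(nuc$atoms))
  if (length(missing))
    stop("missing torsion atom(s): ", paste(missing, collapse = ", "))
  a <- nuc$atoms
  dihedral_angle(a[nm[1], ], a[nm[2], ], a[nm[3], ], a[nm[4], ])
}

#' Classify a glycosidic torsion as syn or anti
#'
#' syn for chi in (-90, +90\], anti otherwise; the two half-circles
#' partition (-180, 180\] completely (boundaries: +90 is syn, -90 and 180
#' are anti).
#'
#' @param chi_deg Torsion in degrees, within (-180, 180\].
#' @return `"syn"` or `"anti"`.
#' @export
classify_glycosidic <- function(chi_deg) {
  if (any(chi_deg <= -180 | chi_deg > 180))
    stop("chi_deg must lie in (-180, 180]")
  ifelse(chi_deg > -90 & chi_deg <= 90, "syn", "anti")
}

## least-squares plane through points: centroid, orthonormal in-plane
## basis (e1, e2) and unit normal; errors on (near-)collinear input
fit_plane <- function(xyz) {
  ctr <- colMeans(xyz)
  sv <- svd(sweep(xyz, 2, ctr))
  if (sv$d[2] < 1e-8 * max(sv$d[1], 1))
    stop("degenerate (collinear) ring atoms")
  list(center = ctr, e1 = sv$v[, 1], e2 = sv$v[, 2], normal = sv$v[, 3])
}

project_to_plane <- function(xyz, plane) {
  rel <- sweep(xyz, 2, plane$center)
  cbind(rel %*% plane$e1, rel %*% plane$e2)
}

polygon_area_signed <- function(p) {
  x <- p[, 1]; y <- p[, 2]
  sum(x * c(y[-1], y[1]) - c(x[-1], x[1]) * y) / 2
}

ensure_ccw <- function(p) {
  if (polygon_area_signed(p) < 0) p[nrow(p):1, , drop = FALSE] else p
}

## Sutherland-Hodgman: clip polygon `subj` by convex polygon `clip`
## (both counterclockwise); returns the intersection area
convex_clip_area <- function(subj, clip) {
  subj <- ensure_ccw(subj); clip <- ensure_ccw(clip)
  out <- subj
  nc <- nrow(clip)
  for (i in seq_len(nc)) {
    if (nrow(out) < 3) return(0)
    a <- clip[i, ]; b <- clip[if (i == nc) 1 else i + 1, ]
    edge <- b - a
    inside <- function(p) edge[1] * (p[2] - a[2]) - edge[2] * (p[1] - a[1]) >= -1e-12
    inp <- out; out <- matrix(numeric(0), ncol = 2)
    np <- nrow(inp)
    for (j in seq_len(np)) {
      P <- inp[j, ]; Q <- inp[if (j == np) 1 else j + 1, ]
      Pin <- inside(P); Qin <- inside(Q)
      if (Pin) out <- rbind(out, P)
      if (Pin != Qin) {
        d <- Q - P
        ## solve cross(edge, P + t d - a) = 0 for the edge crossing
        denom <- edge[1] * d[2] - edge[2] * d[1]
        t <- if (abs(denom) < 1e-300) 0 else
          (edge[2] * (P[1] - a[1]) - edge[1] * (P[2] - a[2])) / denom
        out <- rbind(out, P + t * d)
      }
    }
  }
  if (nrow(out) < 3) 0 else abs(polygon_area_signed(out))
}

base_ring_coords <- function(nuc) {
  lapply(ring_atom_cycles[[nuc$base_type]],
         function(cyc) nuc$atoms[cyc, , drop = FALSE])
}

overlap_in_plane <- function(ringsA, ringsB, plane) {
  m <- matrix(0, length(ringsA), length(ringsB),
              dimnames = list(names(ringsA), names(ringsB)))
  for (i in seq_along(ringsA)) {
    pa <- project_to_plane(ringsA[[i]], plane)
    for (j in seq_along(ringsB)) {
      pb <- project_to_plane(ringsB[[j]], plane)
      m[i, j] <- convex_clip_area(pa, pb)
    }
  }
  m
}

#' Inter-base stacking overlap area
#'
#' Projects both base ring systems onto the least-squares plane of one
#' base and intersects the ring polygons (fused purine rings enter as two
#' convex cycles with disjoint interiors, so the pairwise intersection
#' areas sum to the union overlap); the result is symmetrized by averaging
#' the projection onto A's and B's planes.
#'
#' @param baseA,baseB `nucleotide_structure` objects.
#' @return Overlap area (Angstrom^2) with attributes `components`
#'   (per-ring-pair area matrix, averaged) and `rise_A` (mean inter-plane
#'   distance of the ring centroids).
#' @export
stacking_overlap_area <- function(baseA, baseB) {
  stopifnot(inherits(baseA, "nucleotide_structure"),
            inherits(baseB, "nucleotide_structure"))
  ringsA <- base_ring_coords(baseA)
  ringsB <- base_ring_coords(baseB)
  allA <- do.call(rbind, ringsA); allB <- do.call(rbind, ringsB)
  plA <- fit_plane(allA); plB <- fit_plane(allB)
  mA <- overlap_in_plane(ringsA, ringsB, plA)
  mB <- overlap_in_plane(ringsA, ringsB, plB)
  comp <- (mA + mB) / 2
  riseA <- abs(sum((colMeans(allB) - plA$center) * plA$normal))
  riseB <- abs(sum((colMeans(allA) - plB$center) * plB$normal))
  structure(sum(comp), components = comp, rise_A = (riseA + riseB) / 2)
}

#' Stacking metrics for a base pair
#'
#' @param baseA,baseB `nucleotide_structure` objects.
#' @return One-row data frame: `chi1_deg`, `class1`, `chi2_deg`, `class2`,
#'   `overlap_A2`, `rise_A`.
#' @export
stack_metrics <- function(baseA, baseB) {
  c1 <- chi_torsion(baseA); c2 <- chi_torsion(baseB)
  ov <- stacking_overlap_area(baseA, baseB)
  data.frame(chi1_deg = c1, class1 = classify_glycosidic(c1),
             chi2_deg = c2, class2 = classify_glycosidic(c2),
             overlap_A2 = as.numeric(ov), rise_A = attr(ov, "rise_A"))
}

#' Conformer census over an ensemble of base pairs
#'
#' Classifies each frame by the (syn/anti, syn/anti) orientations of its
#' two bases; frames with missing atoms are skipped and counted.
#'
#' @param frames List of frames, each `list(base1 = , base2 = )` of
#'   `nucleotide_structure` objects.
#' @return An object of class `"conformer_census"`: `counts`, `fractions`
#'   (summing to 1 over classified frames), `n_skipped`.
#' @export
conformer_census <- function(frames) {
  if (!length(frames)) stop("at least one frame required")
  classes <- c("anti-anti", "anti-syn", "syn-anti", "syn-syn")
  counts <- stats::setNames(integer(4), classes)
  skipped <- 0L
  for (fr in frames) {
    cl <- tryCatch({
      k1 <- classify_glycosidic(chi_torsion(fr$base1))
      k2 <- classify_glycosidic(chi_torsion(fr$base2))
      paste(k1, k2, sep = "-")
    }, error = function(e) NA_character_)
    if (is.na(cl)) skipped <- skipped + 1L else counts[cl] <- counts[cl] + 1L
  }
  if (sum(counts) == 0) stop("no classifiable frames")
  structure(list(counts = counts, fractions = counts / sum(counts),
                 n_skipped = skipped),
            class = "conformer_census")
}

#' @export
print.conformer_census <- function(x, ...) {
  cat("Conformer census (base1-base2 glycosidic classes)\n")
  for (l in names(x$counts))
    cat(sprintf("  %-9s %5d  (%.1f %%)\n", l, x$counts[l],
                100 * x$fractions[l]))
  if (x$n_skipped) cat("  skipped frames:", x$n_skipped, "\n")
  invisible(x)
}

#' Read structure frames from a (multi-model) PDB file
#'
#' @param path PDB file; MODEL/ENDMDL blocks become frames.
#' @return List of frames; each frame is a named list of
#'   `nucleotide_structure` objects keyed by residue number.
#' @export
read_structure_frames <- function(path) {
  pdb <- bio3d::read.pdb(path, multi = TRUE, verbose = FALSE)
  at <- pdb$atom
  nmod <- if (length(dim(pdb$xyz)) == 2) nrow(pdb$xyz) else 1
  base_of <- function(resid) {
    r <- sub("^D", "", toupper(resid))
    if (r %in% c("A", "G", "C", "T")) r else NA_character_
  }
  lapply(seq_len(nmod), function(m) {
    xyz <- matrix(pdb$xyz[m, ], ncol = 3, byrow = TRUE)
    frame <- list()
    for (res in unique(at$resno)) {
      sel <- which(at$resno == res)
      bt <- base_of(at$resid[sel[1]])
      if (is.na(bt)) next
      coords <- xyz[sel, , drop = FALSE]
      rownames(coords) <- at$elety[sel]
      frame[[as.character(res)]] <-
        nucleotide_structure(res, bt, coords)
    }
    frame
  })
}

#' Write structure frames as a multi-model PDB file
#'
#' @param frames List of frames as returned by [read_structure_frames()]
#'   or [generate_stacked_frames()].
#' @param path Output path.
#' @export
write_frames_pdb <- function(frames, path) {
  con <- file(path, "w")
  on.exit(close(con))
  resname <- c(A = "DA", G = "DG", C = "DC", T = "DT")
  for (m in seq_along(frames)) {
    writeLines(sprintf("MODEL     %4d", m), con)
    serial <- 0L
    for (nuc in frames[[m]]) {
      for (an in rownames(nuc$atoms)) {
        serial <- serial + 1L
        el <- substr(gsub("[^A-Za-z]", "", an), 1, 1)
        writeLines(sprintf(
          "ATOM  %5d %-4s %3s A%4d    %8.3f%8.3f%8.3f  1.00  0.00          %2s",
          serial, an, resname[[nuc$base_type]],
          as.integer(nuc$residue_id),
          nuc$atoms[an, 1], nuc$atoms[an, 2], nuc$atoms[an, 3], el), con)
      }
    }
    writeLines("ENDMDL", con)
  }
  writeLines("END", con)
  invisible(path)
}

#' Per-frame stacking metrics table
#'
#' @param frames List of frames (`list(base1=, base2=)` pairs).
#' @return Data frame with one row per frame: `frame`, `chi1_deg`,
#'   `class1`, `chi2_deg`, `class2`, `overlap_A2`, `rise_A`.
#' @export
stack_metrics_table <- function(frames) {
  rows <- lapply(seq_along(frames), function(i) {
    m <- stack_metrics(frames[[i]]$base1, frames[[i]]$base2)
    cbind(frame = i, m)
  })
  do.call(rbind, rows)
}
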