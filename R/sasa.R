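#' Shrake-Rupley solvent-accessible surface area
#'
#' Sphere-sampling SASA with a deterministic golden-angle spiral point set (no
#' randomness, so results are exactly reproducible and invariant in
#' distribution under rigid motion and mirroring).
#'
#' @name sasa_module
NULL

# van der Waals radii (Angstrom), element-keyed; a standard protein/nucleic
# acid set in the NACCESS/Chothia family. Editable via the `radii` argument.
.DEFAULT_RADII <- c(
  H = 1.20, C = 1.70, N = 1.55, O = 1.52, P = 1.80, S = 1.80, SE = 1.90,
  F = 1.47, CL = 1.75, BR = 1.85, I = 1.98,
  NA. = 2.27, K = 2.75, MG = 1.73, CA = 2.31, SR = 2.49, RB = 3.03,
  CS = 3.43, ZN = 1.39, MN = 1.39, FE = 1.40, LI = 1.82, TL = 1.96
)

atom_radii <- function(elesy, radii = .DEFAULT_RADII) {
  key <- toupper(elesy)
  key[key == "NA"] <- "NA."
  r <- radii[key]
  if (anyNA(r)) {
    bad <- unique(elesy[is.na(r)])
    stop("no van der Waals radius configured for element(s): ",
         paste(bad, collapse = ", "))
  }
  unname(r)
}

#' Solvent-accessible surface area (Shrake-Rupley)
#'
#' @param model structure_model.
#' @param probe probe radius, Angstrom (default 1.4, a water molecule).
#' @param n_points sample points per atom sphere (default 960).
#' @param include_solvent include waters and ions? Default `FALSE`: solvent is
#'   excluded so that interface areas refer to the macromolecules alone.
#' @param radii named element->radius vector (Angstrom).
#' @return list of class `sasa_result`: `atom_area` (per input atom, Angstrom^2;
#'   0 for excluded solvent), `residue_area` (data.frame), `chain_area` (named
#'   vector), `total`, `probe`, `n_points`.
#' @export
sasa <- function(model, probe = 1.4, n_points = 960, include_solvent = FALSE,
                 radii = .DEFAULT_RADII) {
  a <- model$atoms
  use <- if (include_solvent) rep(TRUE, nrow(a))
  else !(a$polymer_class %in% c("water", "ion"))
  area <- numeric(nrow(a))
  if (any(use)) {
    xyz <- as.matrix(a[use, c("x", "y", "z")])
    r <- atom_radii(a$elesy[use], radii) + probe
    pts <- sphere_points(n_points)
    n <- nrow(xyz)
    # neighbour lists via squared-distance prefilter
    rmax <- max(r)
    for (i in seq_len(n)) {
      d2 <- (xyz[, 1L] - xyz[i, 1L])^2 + (xyz[, 2L] - xyz[i, 2L])^2 +
        (xyz[, 3L] - xyz[i, 3L])^2
      nb <- which(d2 < (r[i] + rmax)^2 & d2 > 1e-12)
      nb <- nb[sqrt(d2[nb]) < r[i] + r[nb]]
      p <- sweep(pts * r[i], 2L, xyz[i, ], "+")
      acc <- rep(TRUE, n_points)
      for (j in nb) {
        dj2 <- (p[, 1L] - xyz[j, 1L])^2 + (p[, 2L] - xyz[j, 2L])^2 +
          (p[, 3L] - xyz[j, 3L])^2
        acc <- acc & dj2 > r[j]^2
        if (!any(acc)) break
      }
      area[which(use)[i]] <- 4 * pi * r[i]^2 * sum(acc) / n_points
    }
  }
  key <- paste(a$chain, a$resno, a$insert, sep = "\r")
  first <- !duplicated(key)
  res_area <- data.frame(chain = a$chain[first], resno = a$resno[first],
                         insert = a$insert[first], resid = a$resid[first],
                         area = as.numeric(tapply(area, factor(key, levels = key[first]),
                                                  sum)),
                         stringsAsFactors = FALSE)
  ch <- tapply(area, a$chain, sum)
  structure(list(atom_area = area, residue_area = res_area,
                 chain_area = ch, total = sum(area), probe = probe,
                 n_points = n_points),
            class = "sasa_result")
}

#' @export
print.sasa_result <- function(x, ...) {
  cat(sprintf("SASA: %.1f A^2 total (probe %.2f A, %d points/atom)\n",
              x$total, x$probe, x$n_points))
  print(round(x$chain_area, 1))
  invisible(x)
}
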