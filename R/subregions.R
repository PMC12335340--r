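## Mapping tumor-subregion labels onto the MRSI grid: per-voxel subregion
## fractions by exact cell counting, exclusion of VOI-edge voxels, the
## majority-fraction voxel-assignment rule with its tie extension, and
## per-subregion metabolite summaries.

SUBREGION_CLASSES <- c("ET", "NETC", "SNFH", "CL")

#' Per-voxel subregion fractions from a high-resolution label map
#'
#' The label volume must be aligned to the grid with dimensions an integer
#' multiple of the grid dimensions; the fraction of each class within each
#' voxel footprint is computed by exact integer cell counting, so the
#' fractions sum to 1 per voxel.
#'
#' @param labels Character (or factor) matrix of high-resolution labels.
#' @param grid_dims MRSI grid dimensions (rows, cols).
#' @param classes Label classes to report.
#' @return Array rows x cols x classes of fractions, with attribute
#'   `"counts"` holding the integer counts.
#' @export
voxel_subregion_fractions <- function(labels, grid_dims,
                                      classes = SUBREGION_CLASSES) {
  nr <- nrow(labels); nc <- ncol(labels)
  if (nr %% grid_dims[1] != 0 || nc %% grid_dims[2] != 0)
    stop("label dimensions must be an integer multiple of the grid")
  fr <- nr %/% grid_dims[1]; fc <- nc %/% grid_dims[2]
  counts <- array(0L, c(grid_dims, length(classes)),
                  dimnames = list(NULL, NULL, classes))
  for (i in seq_len(grid_dims[1])) for (j in seq_len(grid_dims[2])) {
    block <- labels[(i - 1) * fr + seq_len(fr), (j - 1) * fc + seq_len(fc)]
    tb <- table(factor(as.vector(block), levels = classes))
    counts[i, j, ] <- as.integer(tb)
  }
  fractions <- counts / (fr * fc)
  attr(fractions, "counts") <- counts
  attr(fractions, "cells_per_voxel") <- fr * fc
  fractions
}

#' Interior of a VOI mask (edge voxels excluded)
#'
#' Removes voxels 8-adjacent to any position outside the mask (edge
#' voxels suffer from imperfect slice/excitation profiles).  A 12 x 12
#' VOI therefore retains a 10 x 10 = 100 voxel interior.
#'
#' @param voi_mask Logical matrix.
#' @return Logical matrix of interior voxels; warns when empty.
#' @export
exclude_voi_edge <- function(voi_mask) {
  nr <- nrow(voi_mask); nc <- ncol(voi_mask)
  interior <- matrix(FALSE, nr, nc)
  for (i in seq_len(nr)) for (j in seq_len(nc)) {
    if (!voi_mask[i, j]) next
    ok <- TRUE
    for (di in -1:1) for (dj in -1:1) {
      ii <- i + di; jj <- j + dj
      if (ii < 1 || ii > nr || jj < 1 || jj > nc || !voi_mask[ii, jj])
        ok <- FALSE
    }
    interior[i, j] <- ok
  }
  if (!any(interior)) warning("VOI too small: empty interior")
  interior
}

#' Assign voxels to tumor subregions by the majority-fraction rule
#'
#' Per subregion, candidate voxels are those inside the VOI interior,
#' QC-accepted, with a subregion fraction strictly above `min_fraction`.
#' The `top_n` voxels with maximal fraction are selected; when the
#' `top_n`-th fraction is tied with subsequent voxels they are included
#' too (ties compared on exact integer cell counts).  A subregion with no
#' candidate is marked excluded.
#'
#' @param fractions Output of [voxel_subregion_fractions()].
#' @param qc_mask Logical matrix of QC-accepted voxels.
#' @param interior_mask Logical matrix from [exclude_voi_edge()]; defaults
#'   to all-TRUE.
#' @param min_fraction Assignment threshold (default 0.5, strict).
#' @param top_n Number of maximal-fraction voxels retained (default 3).
#' @param classes Subregions to process.
#' @return Object of class `subregion_selection`: per subregion a data
#'   frame (voxel_i, voxel_j, fraction), plus `excluded` with reasons.
#' @export
assign_subregion_voxels <- function(fractions, qc_mask,
                                    interior_mask = NULL,
                                    min_fraction = 0.5, top_n = 3,
                                    classes = c("ET", "NETC", "SNFH")) {
  counts <- attr(fractions, "counts")
  if (is.null(counts)) {
    counts <- round(fractions * 1e9)  # fall back to scaled fractions
    attr(fractions, "cells_per_voxel") <- 1e9
  }
  cpv <- attr(fractions, "cells_per_voxel")
  dims <- dim(fractions)[1:2]
  interior_mask <- interior_mask %||% matrix(TRUE, dims[1], dims[2])
  sel <- list(); excluded <- list()
  for (cl in classes) {
    cnt <- matrix(counts[, , cl], dims[1], dims[2])
    cand <- which(interior_mask & qc_mask & (cnt > min_fraction * cpv),
                  arr.ind = TRUE)
    if (nrow(cand) == 0) {
      excluded[[cl]] <- "no voxel above the fraction threshold"
      next
    }
    cc <- cnt[cand]
    ord <- order(cc, decreasing = TRUE)
    cand <- cand[ord, , drop = FALSE]; cc <- cc[ord]
    n_take <- min(top_n, length(cc))
    thr <- cc[n_take]
    take <- which(cc >= thr)   # extends through ties with the top_n-th
    sel[[cl]] <- data.frame(voxel_i = cand[take, 1],
                            voxel_j = cand[take, 2],
                            fraction = cc[take] / cpv)
  }
  structure(list(selected = sel, excluded = excluded,
                 min_fraction = min_fraction, top_n = top_n),
            class = "subregion_selection")
}

#' @export
print.subregion_selection <- function(x, ...) {
  cat("<subregion_selection>\n")
  for (cl in names(x$selected))
    cat(" ", cl, ":", nrow(x$selected[[cl]]), "voxel(s)\n")
  for (cl in names(x$excluded))
    cat(" ", cl, ": excluded (", x$excluded[[cl]], ")\n")
  invisible(x)
}

#' Per-subregion metabolite summaries over selected voxels
#'
#' @param selection A [assign_subregion_voxels()] result, optionally with
#'   an extra `CL` entry; alternatively a named list of voxel data frames.
#' @param conc_maps Named list of concentration matrices (mM).
#' @return Data frame (subregion, metabolite, mean, sd, n); empty
#'   selections are omitted with a message attribute.
#' @export
subregion_levels <- function(selection, conc_maps) {
  sel <- if (inherits(selection, "subregion_selection")) selection$selected
         else selection
  rows <- list()
  for (cl in names(sel)) {
    vox <- sel[[cl]]
    if (is.null(vox) || nrow(vox) == 0) next
    for (met in names(conc_maps)) {
      vals <- conc_maps[[met]][cbind(vox$voxel_i, vox$voxel_j)]
      vals <- vals[!is.na(vals)]
      if (length(vals) == 0) next
      rows[[length(rows) + 1]] <- data.frame(
        subregion = cl, metabolite = met, mean = mean(vals),
        sd = if (length(vals) > 1) stats::sd(vals) else 0,
        n = length(vals))
    }
  }
  do.call(rbind, rows)
}
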