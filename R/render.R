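# Virtual-microscopy rendering: one spherical volume element of an organelle
# (default radius 250 nm, roughly a confocal observation volume) with
# molecules drawn to scale.

with_seed <- function(seed, code) {
  if (!exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
    stats::runif(1)
  }
  old <- get(".Random.seed", envir = globalenv())
  on.exit(assign(".Random.seed", old, envir = globalenv()))
  set.seed(seed)
  force(code)
}

#' Poisson-sample the molecule counts in a voxel
#'
#' A voxel is a random sample of the organelle, so each species contributes
#' a Poisson count with mean c_i * V_voxel.
#'
#' @param concentration_uM named vector of species concentrations in uM
#' @param voxel_radius voxel sphere radius in nm
#' @return named integer vector of counts
#' @export
sample_voxel_counts <- function(concentration_uM, voxel_radius = 250) {
  lambda <- uM_to_per_nm3(concentration_uM) *
    (4 * pi / 3) * voxel_radius^3
  setNames(stats::rpois(length(lambda), lambda), names(concentration_uM))
}

# uniform points in a sphere of radius R: direction x radius ~ R * U^(1/3)
runif_sphere <- function(n, radius) {
  if (n == 0L) return(matrix(numeric(0), ncol = 3))
  v <- matrix(stats::rnorm(3 * n), ncol = 3)
  v <- v / sqrt(rowSums(v^2))
  v * radius * stats::runif(n)^(1 / 3)
}

default_class_colors <- function(species, class) {
  cols <- character(length(species))
  cols[class == "nucleosome"] <- "gray60"
  cols[class == "rna"] <- "darkred"
  prot <- which(class == "protein")
  if (length(prot))
    cols[prot] <- grDevices::hcl.colors(max(length(prot), 2L), "Dark 3")[
      seq_along(prot)]
  setNames(cols, species)
}

#' Render a virtual-microscopy voxel image
#'
#' Draws Poisson-sampled counts of each species, placed uniformly at random
#' inside a sphere, as an orthographic projection with molecules to scale.
#' Placement attempts hard-sphere rejection against already placed
#' molecules up to a bounded attempt budget per molecule, after which
#' overlap is allowed with a warning. Nucleosomes are gray, RNAs dark red,
#' proteins take a per-species palette. Deterministic for a given seed.
#'
#' @param components data frame with columns `species`, `class`,
#'   `concentration_uM` and `diameter` (nm)
#' @param voxel_radius voxel sphere radius in nm
#' @param seed integer seed
#' @param px image edge length in pixels
#' @param path optional PNG output path
#' @param max_attempts placement attempts per molecule before allowing
#'   overlap
#' @return the image as a `px` x `px` x 3 array in \[0, 1\], invisibly;
#'   written to `path` when given
#' @export
render_voxel <- function(components, voxel_radius = 250, seed = 1L,
                         px = 400L, path = NULL, max_attempts = 50L) {
  img <- array(1, dim = c(px, px, 3))
  if (nrow(components) > 0) with_seed(seed, {
    counts <- sample_voxel_counts(
      setNames(components$concentration_uM, components$species), voxel_radius)
    ord <- order(components$diameter, decreasing = TRUE)
    colors <- default_class_colors(components$species, components$class)
    placed <- matrix(numeric(0), ncol = 4)  # x, y, z, radius
    idx <- integer(0)                        # species row per placed molecule
    overlapped <- FALSE
    for (i in ord) {
      n_i <- counts[[components$species[i]]]
      r_i <- components$diameter[i] / 2
      for (k in seq_len(n_i)) {
        pos <- NULL
        for (a in seq_len(max_attempts)) {
          cand <- runif_sphere(1, voxel_radius)
          if (nrow(placed) == 0L ||
              all(sqrt(rowSums(sweep(placed[, 1:3, drop = FALSE], 2,
                                     cand)^2)) >= placed[, 4] + r_i)) {
            pos <- cand
            break
          }
        }
        if (is.null(pos)) {
          overlapped <- TRUE
          pos <- runif_sphere(1, voxel_radius)
        }
        placed <- rbind(placed, c(pos, r_i))
        idx <- c(idx, i)
      }
    }
    if (overlapped)
      warning("placement budget exhausted for some molecules; overlap allowed")
    if (nrow(placed)) {
      zord <- order(placed[, 3])  # painter's order: far first
      scale <- px / (2 * voxel_radius)
      xs <- seq_len(px)
      for (m in zord) {
        cx <- (placed[m, 1] + voxel_radius) * scale
        cy <- (placed[m, 2] + voxel_radius) * scale
        rp <- max(placed[m, 4] * scale, 0.5)
        rows <- xs[abs(xs - 0.5 - cy) <= rp]
        if (!length(rows)) next
        rgb <- grDevices::col2rgb(colors[[components$species[idx[m]]]]) / 255
        for (row in rows) {
          half <- sqrt(rp^2 - (row - 0.5 - cy)^2)
          cols <- xs[abs(xs - 0.5 - cx) <= half]
          if (length(cols)) for (ch in 1:3) img[row, cols, ch] <- rgb[ch]
        }
      }
    }
  })
  if (!is.null(path)) png::writePNG(img, path)
  invisible(img)
}
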