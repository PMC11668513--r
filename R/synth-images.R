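# Synthetic 3D two-channel image stacks: ellipsoidal nuclei (DAPI
# channel), Gaussian-profile foci (target channel) and an optional second
# channel sharing a configurable fraction of focus positions, all with a
# planted truth table.

# Ellipsoid membership of every voxel, as a logical array.
ellipsoid_mask <- function(dims, center, semi_axes) {
  x <- (seq_len(dims[1L]) - center[1L]) / semi_axes[1L]
  y <- (seq_len(dims[2L]) - center[2L]) / semi_axes[2L]
  z <- (seq_len(dims[3L]) - center[3L]) / semi_axes[3L]
  outer(outer(x^2, y^2, `+`), z^2, `+`) <= 1
}

# Add a truncated Gaussian focus profile to a volume.
add_focus <- function(vol, center, peak, sigma) {
  d <- dim(vol)
  r <- ceiling(3 * sigma)
  xs <- max(1L, center[1L] - r):min(d[1L], center[1L] + r)
  ys <- max(1L, center[2L] - r):min(d[2L], center[2L] + r)
  zs <- max(1L, center[3L] - r):min(d[3L], center[3L] + r)
  dx2 <- (xs - center[1L])^2
  dy2 <- (ys - center[2L])^2
  dz2 <- (zs - center[3L])^2
  blob <- peak * exp(-outer(outer(dx2, dy2, `+`), dz2, `+`) / (2 * sigma^2))
  vol[xs, ys, zs] <- vol[xs, ys, zs] + blob
  vol
}

# Draw `n` focus centres inside a shrunken ellipsoid with a minimum
# pairwise separation; errors when the packing is infeasible.
place_foci <- function(n, center, semi_axes, min_sep, max_tries = 5000L) {
  if (n == 0L) {
    return(matrix(integer(), ncol = 3L))
  }
  pts <- matrix(0L, nrow = 0L, ncol = 3L)
  tries <- 0L
  while (nrow(pts) < n) {
    tries <- tries + 1L
    if (tries > max_tries) {
      stop("cannot place ", n, " foci with separation ", min_sep,
           " inside the nucleus (packing infeasible)", call. = FALSE)
    }
    u <- runif(3L, -0.75, 0.75)
    cand <- round(center + u * semi_axes)
    if (sum(((cand - center) / semi_axes)^2) > 0.75^2) next
    if (nrow(pts) > 0L &&
        min(sqrt(rowSums((pts - matrix(cand, nrow(pts), 3L, byrow = TRUE))^2))) < min_sep) {
      next
    }
    pts <- rbind(pts, cand)
  }
  pts
}

#' Generate a synthetic 3D image stack with planted nuclei and foci
#'
#' Builds a DAPI channel with `n_nuclei` ellipsoidal nuclei, a target
#' channel with `n_foci` Gaussian-profile foci per nucleus (peak intensity
#' `peak_to_background` times the intra-nuclear background), an optional
#' second channel sharing a fraction `coloc_fraction` of focus positions,
#' and Gaussian read noise everywhere (clamped at zero).  Nuclei are placed
#' side by side along x; an error is raised when they cannot be packed.
#'
#' @param dims Volume dimensions `c(nx, ny, nz)` (default `c(96, 96, 32)`).
#' @param n_nuclei Number of nuclei (default 1).
#' @param n_foci Foci per nucleus (default 5; may be a vector, one count
#'   per nucleus).
#' @param focus_radius Focus radius in voxels (default 3; the Gaussian
#'   profile has `sigma = focus_radius / 2`).
#' @param peak_to_background Focus peak over intra-nuclear background
#'   (default 10).
#' @param background Intra-nuclear background intensity (default 50).
#' @param noise_sd Additive Gaussian noise SD (default `background / 5`,
#'   i.e. SNR 5 on the nuclear signal).
#' @param coloc_fraction Fraction of per-nucleus foci shared by the second
#'   channel (default `NA`: no second channel generated).
#' @param seed RNG seed.
#' @return List: `dapi`, `target`, `channel2` (or `NULL`), `nuclei_mask`
#'   (integer truth labels), `foci` (truth table: `nucleus`, `x`, `y`,
#'   `z`, `shared`).
#' @export
generate_image_stack <- function(dims = c(96L, 96L, 32L), n_nuclei = 1L,
                                 n_foci = 5L, focus_radius = 3,
                                 peak_to_background = 10, background = 50,
                                 noise_sd = background / 5,
                                 coloc_fraction = NA, seed = 1L) {
  if (length(n_foci) == 1L) {
    n_foci <- rep(n_foci, n_nuclei)
  }
  stopifnot(length(n_foci) == n_nuclei)
  slot <- dims[1L] %/% n_nuclei
  semi <- c(slot / 2 - 4, dims[2L] / 2 - 6, dims[3L] / 2 - 3)
  if (any(semi < 4)) {
    stop("cannot pack ", n_nuclei, " nuclei into a ",
         paste(dims, collapse = "x"), " volume", call. = FALSE)
  }
  with_seed(seed, {
    nuclei_mask <- array(0L, dim = dims)
    dapi <- array(0, dim = dims)
    target <- array(0, dim = dims)
    channel2 <- if (is.na(coloc_fraction)) NULL else array(0, dim = dims)
    peak <- peak_to_background * background - background
    sigma_f <- focus_radius / 2
    foci_rows <- list()

    for (i in seq_len(n_nuclei)) {
      center <- c((i - 0.5) * slot, dims[2L] / 2, dims[3L] / 2)
      mask <- ellipsoid_mask(dims, center, semi)
      nuclei_mask[mask] <- i
      dapi[mask] <- dapi[mask] + 5 * noise_sd
      target[mask] <- target[mask] + background
      if (!is.null(channel2)) {
        channel2[mask] <- channel2[mask] + background
      }
      pts <- place_foci(n_foci[i], center, semi, min_sep = 3 * focus_radius)
      n_shared <- if (is.na(coloc_fraction)) 0L else round(coloc_fraction * n_foci[i])
      for (f in seq_len(nrow(pts))) {
        target <- add_focus(target, pts[f, ], peak, sigma_f)
        if (!is.null(channel2) && f <= n_shared) {
          channel2 <- add_focus(channel2, pts[f, ], peak, sigma_f)
        }
        foci_rows[[length(foci_rows) + 1L]] <- data.frame(
          nucleus = i, x = pts[f, 1L], y = pts[f, 2L], z = pts[f, 3L],
          shared = f <= n_shared
        )
      }
      if (!is.null(channel2) && n_foci[i] > n_shared) {
        # unshared channel-2 foci at independent positions
        pts2 <- place_foci(n_foci[i] - n_shared, center, semi,
                           min_sep = 3 * focus_radius)
        for (f in seq_len(nrow(pts2))) {
          channel2 <- add_focus(channel2, pts2[f, ], peak, sigma_f)
        }
      }
    }

    noisy <- function(v) {
      if (is.null(v)) {
        return(NULL)
      }
      pmax(v + array(rnorm(prod(dims), 0, noise_sd), dim = dims), 0)
    }
    list(
      dapi = noisy(dapi),
      target = noisy(target),
      channel2 = noisy(channel2),
      nuclei_mask = nuclei_mask,
      foci = if (length(foci_rows)) {
        do.call(rbind, foci_rows)
      } else {
        data.frame(nucleus = integer(), x = integer(), y = integer(),
                   z = integer(), shared = logical())
      }
    )
  })
}
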