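#' Voxel image container
#'
#' A 3D scalar grid with isotropic-or-not voxel spacing, a role tag saying
#' what the values mean, and (where applicable) an acquisition time in hours
#' post administration. This is the common currency of the pipeline: count
#' rate maps straight off the camera, calibrated activity maps, density maps
#' and dose-rate maps all travel in this container.
#'
#' @param data 3D numeric array.
#' @param spacing_mm Voxel spacing in mm; length 1 (isotropic) or 3.
#' @param role One of `"counts"`, `"activity"`, `"density"`, `"dose-rate"`.
#'   Counts, activity and density grids must be non-negative.
#' @param time_h Acquisition time, hours post administration (NA where not
#'   applicable, e.g. density maps).
#' @return An object of class `voxel_image`.
#' @export
voxel_image <- function(data, spacing_mm,
                        role = c("activity", "counts", "density", "dose-rate"),
                        time_h = NA_real_) {
  role <- match.arg(role)
  if (!is.array(data) || length(dim(data)) != 3L)
    stop("`data` must be a 3D array")
  if (length(spacing_mm) == 1L) spacing_mm <- rep(spacing_mm, 3L)
  if (length(spacing_mm) != 3L || any(spacing_mm <= 0))
    stop("`spacing_mm` must be positive, length 1 or 3")
  if (role %in% c("counts", "activity", "density") && any(data < 0, na.rm = TRUE))
    stop(sprintf("a %s image must be non-negative", role))
  structure(
    list(data = data, spacing_mm = as.numeric(spacing_mm), role = role,
         time_h = as.numeric(time_h)),
    class = "voxel_image"
  )
}

#' Voxel volume of an image
#'
#' @param x A [voxel_image()] (or a numeric spacing vector).
#' @return Volume of one voxel in mL.
#' @export
voxel_volume_ml <- function(x) {
  sp <- if (inherits(x, "voxel_image")) x$spacing_mm else x
  prod(sp) / 1000
}

#' @export
print.voxel_image <- function(x, ...) {
  d <- dim(x$data)
  cat(sprintf("<voxel_image> %s, %d x %d x %d voxels @ %s mm",
              x$role, d[1], d[2], d[3],
              paste(format(x$spacing_mm), collapse = " x ")))
  if (!is.na(x$time_h)) cat(sprintf(", t = %g h", x$time_h))
  cat(sprintf("\n  total = %g, max = %g\n", sum(x$data), max(x$data)))
  invisible(x)
}

## TRUE if two images (or image + mask array) share grid shape and spacing
same_grid <- function(a, b, tol = 1e-9) {
  da <- if (inherits(a, "voxel_image")) dim(a$data) else dim(a)
  db <- if (inherits(b, "voxel_image")) dim(b$data) else dim(b)
  if (!identical(as.integer(da), as.integer(db))) return(FALSE)
  if (inherits(a, "voxel_image") && inherits(b, "voxel_image"))
    return(all(abs(a$spacing_mm - b$spacing_mm) <= tol * pmax(a$spacing_mm, 1)))
  TRUE
}

## ---- low-level array ops shared by the blur and the dose kernel ----------

## Shift a 3D array by integer offsets (positive = towards higher indices),
## filling with zeros: out[r] = a[r - off].
shift3 <- function(a, off) {
  d <- dim(a)
  out <- array(0, d)
  src <- dst <- vector("list", 3L)
  for (ax in 1:3) {
    o <- off[ax]
    if (abs(o) >= d[ax]) return(out)
    if (o >= 0) {
      src[[ax]] <- seq_len(d[ax] - o)
      dst[[ax]] <- seq_len(d[ax] - o) + o
    } else {
      src[[ax]] <- seq_len(d[ax] + o) - o
      dst[[ax]] <- seq_len(d[ax] + o)
    }
  }
  out[dst[[1]], dst[[2]], dst[[3]]] <- a[src[[1]], src[[2]], src[[3]]]
  out
}

## Separable Gaussian blur with a normalised, truncated (+-4 sigma) kernel.
## Zero padding at the grid edge; total is conserved for objects clear of
## the boundary because each 1D kernel sums to exactly 1.
gaussian_blur3 <- function(a, sigma_mm, spacing_mm) {
  if (sigma_mm < 0) stop("blur sigma must be >= 0")
  if (sigma_mm == 0) return(a)
  for (ax in 1:3) {
    s <- sigma_mm / spacing_mm[ax]
    r <- max(1L, as.integer(ceiling(4 * s)))
    x <- (-r):r
    k <- exp(-x^2 / (2 * s^2))
    k <- k / sum(k)
    out <- array(0, dim(a))
    for (m in seq_along(x)) {
      off <- c(0L, 0L, 0L)
      off[ax] <- x[m]
      out <- out + k[m] * shift3(a, off)
    }
    a <- out
  }
  a
}

## Label connected components of a logical 3D mask (6-connectivity).
## Returns an integer array, 0 = background. BFS over linear indices.
label_components6 <- function(mask) {
  d <- dim(mask)
  nx <- d[1]; nxy <- d[1] * d[2]
  lab <- array(0L, d)
  idx <- which(mask)
  if (!length(idx)) return(lab)
  cur <- 0L
  for (start in idx) {
    if (lab[start] > 0L) next
    cur <- cur + 1L
    queue <- integer(256L)
    queue[1L] <- start
    lab[start] <- cur
    head <- 1L; tail <- 1L
    while (head <= tail) {
      v <- queue[head]; head <- head + 1L
      v0 <- v - 1L
      i <- v0 %% nx + 1L
      j <- (v0 %/% nx) %% d[2] + 1L
      k <- v0 %/% nxy + 1L
      nb <- c(if (i > 1L) v - 1L, if (i < d[1]) v + 1L,
              if (j > 1L) v - nx, if (j < d[2]) v + nx,
              if (k > 1L) v - nxy, if (k < d[3]) v + nxy)
      for (w in nb) {
        if (mask[w] && lab[w] == 0L) {
          lab[w] <- cur
          tail <- tail + 1L
          if (tail > length(queue)) queue <- c(queue, integer(length(queue)))
          queue[tail] <- w
        }
      }
    }
  }
  lab
}
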