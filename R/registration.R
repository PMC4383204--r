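#' Rigid 2-D transform
#'
#' A rotation by `theta` degrees about `center` followed by a translation of
#' `(dx, dy)` pixels: a point `q` of the input maps to
#' `p = R(theta) (q - c) + c + t` in the output, so resampling the input
#' under the transform fills `out(p) = img(R(-theta) (p - c - t) + c)`.
#' `center` is in 1-based `(y, x)` pixel coordinates; `dy`/`dx` move along
#' the row/column axes.
#'
#' @param dx,dy translation in pixels.
#' @param theta rotation in degrees (counter-clockwise in `(y, x)` with y
#'   increasing down the rows).
#' @param center `(y, x)` rotation center, 1-based pixels.
#' @return An object of class `rigid2d`.
#' @export
rigid2d <- function(dx = 0, dy = 0, theta = 0, center = c(0, 0)) {
  structure(list(dx = as.numeric(dx), dy = as.numeric(dy),
                 theta = as.numeric(theta), center = as.numeric(center)),
            class = "rigid2d")
}

#' @export
print.rigid2d <- function(x, ...) {
  cat(sprintf("<rigid2d> dx %.4g px, dy %.4g px, theta %.4g deg, center (%g, %g)\n",
              x$dx, x$dy, x$theta, x$center[1], x$center[2]))
  invisible(x)
}

rot2 <- function(theta_deg) {
  th <- theta_deg * pi / 180
  matrix(c(cos(th), sin(th), -sin(th), cos(th)), 2, 2)  # acts on (y, x)
}

#' Invert a rigid 2-D transform
#' @param tf a [rigid2d()].
#' @return the inverse [rigid2d()] about the same center.
#' @export
invert_rigid2d <- function(tf) {
  t_inv <- -rot2(-tf$theta) %*% c(tf$dy, tf$dx)
  rigid2d(dx = t_inv[2], dy = t_inv[1], theta = -tf$theta, center = tf$center)
}

#' Compose rigid 2-D transforms (`a` after `b`)
#'
#' Both transforms must share the same rotation center.
#' @param a,b [rigid2d()] objects; the result applies `b` first, then `a`.
#' @export
compose_rigid2d <- function(a, b) {
  if (max(abs(a$center - b$center)) > 1e-9)
    stop("can only compose transforms about the same center", call. = FALSE)
  t_new <- rot2(a$theta) %*% c(b$dy, b$dx) + c(a$dy, a$dx)
  rigid2d(dx = t_new[2], dy = t_new[1], theta = a$theta + b$theta,
          center = a$center)
}

#' Resample an image under a rigid transform
#'
#' @param img numeric matrix `[y, x]` (or `[y, x, channel]` array).
#' @param tf a [rigid2d()].
#' @param interpolation `"linear"` or `"nearest"` (use nearest for labels so
#'   the code set is preserved).
#' @param fill value used outside the input (background 0 by default).
#' @return resampled image, same shape as the input.
#' @export
apply_rigid2d <- function(img, tf, interpolation = c("linear", "nearest"),
                          fill = 0) {
  interpolation <- match.arg(interpolation)
  nearest <- interpolation == "nearest"
  f <- function(m)
    cpp_resample_rigid2d(m, tf$dx, tf$dy, tf$theta,
                         tf$center[1] - 1, tf$center[2] - 1, nearest, fill)
  if (length(dim(img)) == 3) {
    out <- array(0, dim(img))
    for (c in seq_len(dim(img)[3])) out[, , c] <- f(img[, , c])
    out
  } else f(as.matrix(img))
}

# Signed FFT frequency indices for length n.
fft_freqs <- function(n) {
  f <- seq_len(n) - 1
  f[f > n / 2] <- f[f > n / 2] - n
  f
}

# Evaluate the circular cross-correlation at arbitrary real shifts by a
# direct DFT zoom of the spectral product P = F(fixed) * Conj(F(moving)).
xcorr_zoom <- function(P, sy, sx) {
  ny <- nrow(P); nx <- ncol(P)
  Ey <- exp(2i * pi * outer(fft_freqs(ny), sy) / ny)   # ny x |sy|
  Ex <- exp(2i * pi * outer(fft_freqs(nx), sx) / nx)   # nx x |sx|
  Re(t(Ey) %*% P %*% Ex) / (ny * nx)
}

# Circular cross-correlation of two equal-shape zero-mean images via FFT,
# returning the best shift (moving by (dy, dx) aligns it onto fixed) with
# subpixel refinement by local DFT upsampling, and the normalized peak score.
xcorr_shift <- function(fixed, moving, refine = TRUE) {
  ny <- nrow(fixed); nx <- ncol(fixed)
  Ff <- stats::fft(fixed)
  Fm <- stats::fft(moving)
  P <- Ff * Conj(Fm)
  cc <- Re(stats::fft(P, inverse = TRUE)) / (ny * nx)
  nf <- sqrt(sum(fixed^2)) * sqrt(sum(moving^2))
  if (nf == 0) return(list(dy = 0, dx = 0, score = 0))
  peak <- which.max(cc)
  py <- (peak - 1) %% ny; px <- (peak - 1) %/% ny
  sy <- if (py > ny / 2) py - ny else py
  sx <- if (px > nx / 2) px - nx else px
  val <- cc[peak]
  if (refine) {
    for (h in c(0.5, 0.05)) {
      gy <- sy + seq(-h * 10, h * 10, by = h)
      gx <- sx + seq(-h * 10, h * 10, by = h)
      cz <- xcorr_zoom(P, gy, gx)
      w <- which(cz == max(cz), arr.ind = TRUE)[1, ]
      sy <- gy[w[1]]; sx <- gx[w[2]]
      val <- max(cz)
    }
  }
  list(dy = sy, dx = sx, score = val / nf)
}

hann2 <- function(ny, nx) {
  wy <- 0.5 * (1 - cos(2 * pi * (seq_len(ny) - 1) / (ny - 1)))
  wx <- 0.5 * (1 - cos(2 * pi * (seq_len(nx) - 1) / (nx - 1)))
  outer(wy, wx)
}

#' Rigid alignment of one section onto another
#'
#' Finds the rigid transform mapping `moving` onto `fixed` by exhaustive
#' search over a rotation grid (step <= 0.25 degrees within
#' `±max_rotation_deg`) scored by Hann-windowed normalized spectral
#' cross-correlation, followed by iterative refinement: the moving image is
#' resampled under the current estimate and the residual translation
#' (subpixel, by local DFT zoom of the correlation) and residual rotation
#' (parabolic on the score) are measured and folded in. Re-measuring near
#' identity cancels the window- and interpolation-induced biases of a
#' single-pass estimate. Deterministic. When `roi` is given
#' (`c(y0, x0, height, width)`, 1-based), matching is computed on the crop
#' but the returned transform is expressed in full-image coordinates (its
#' center is the crop center).
#'
#' @param fixed,moving numeric matrices of the same shape (use one channel).
#' @param max_rotation_deg rotation search half-range, degrees.
#' @param roi optional `c(y0, x0, height, width)` crop, 1-based.
#' @param rotation_step_deg rotation grid step (capped at 0.25).
#' @param refine_iter residual refinement passes (default 5).
#' @return a [rigid2d()] such that `apply_rigid2d(moving, tf)` matches
#'   `fixed`, with an extra `score` attribute (peak normalized correlation).
#' @export
align_pair <- function(fixed, moving, max_rotation_deg = 5, roi = NULL,
                       rotation_step_deg = 0.25, refine_iter = 5L) {
  fixed <- as.matrix(fixed); moving <- as.matrix(moving)
  if (!all(dim(fixed) == dim(moving)))
    stop("fixed and moving must have the same shape", call. = FALSE)
  if (is.null(roi)) roi <- c(1, 1, nrow(fixed), ncol(fixed))
  ys <- roi[1]:(roi[1] + roi[3] - 1); xs <- roi[2]:(roi[2] + roi[4] - 1)
  f <- fixed[ys, xs, drop = FALSE]; m <- moving[ys, xs, drop = FALSE]
  if (stats::sd(f) == 0 || stats::sd(m) == 0)
    stop("no registration signal: image region is constant", call. = FALSE)
  W <- hann2(nrow(f), ncol(f))
  fw <- (f - mean(f)) * W
  ctr_local <- c((nrow(f) + 1) / 2, (ncol(f) + 1) / 2)
  prep <- function(img) (img - mean(img)) * W
  score_vs_fixed <- function(mr, refine = FALSE)
    xcorr_shift(fw, prep(mr), refine = refine)

  # coarse rotation grid
  step <- min(rotation_step_deg, 0.25)
  thetas <- seq(-max_rotation_deg, max_rotation_deg, by = step)
  sc <- vapply(thetas, function(th) {
    mr <- if (th == 0) m else
      apply_rigid2d(m, rigid2d(0, 0, th, ctr_local), "linear", 0)
    score_vs_fixed(mr)$score
  }, 0)
  i <- which.max(sc)
  cur <- rigid2d(0, 0, thetas[i], ctr_local)
  s0 <- score_vs_fixed(if (thetas[i] == 0) m else
    apply_rigid2d(m, cur, "linear", 0), refine = TRUE)
  cur <- compose_rigid2d(rigid2d(s0$dx, s0$dy, 0, ctr_local), cur)
  best_score <- s0$score

  # residual refinement near identity
  h <- step
  for (it in seq_len(refine_iter)) {
    mr <- apply_rigid2d(m, cur, "linear", 0)
    if (max_rotation_deg > 0) {
      tri <- c(-h, 0, h)
      rs <- lapply(tri, function(dth) {
        mt <- if (dth == 0) mr else
          apply_rigid2d(m, compose_rigid2d(rigid2d(0, 0, dth, ctr_local), cur),
                        "linear", 0)
        score_vs_fixed(mt, refine = TRUE)
      })
      svals <- vapply(rs, `[[`, 0, "score")
      j <- which.max(svals)
      dth <- tri[j]
      den <- svals[1] - 2 * svals[2] + svals[3]
      if (j == 2 && den < 0)
        dth <- max(-h, min(h, 0.5 * h * (svals[1] - svals[3]) / den))
      if (dth != 0) {
        cur <- compose_rigid2d(rigid2d(0, 0, dth, ctr_local), cur)
        mr <- apply_rigid2d(m, cur, "linear", 0)
      }
    }
    res <- score_vs_fixed(mr, refine = TRUE)
    cur <- compose_rigid2d(rigid2d(res$dx, res$dy, 0, ctr_local), cur)
    best_score <- res$score
    h <- h / 2
    if (abs(res$dx) < 0.01 && abs(res$dy) < 0.01) break
  }
  ctr_global <- c(roi[1] + (roi[3] - 1) / 2, roi[2] + (roi[4] - 1) / 2)
  out <- rigid2d(dx = cur$dx, dy = cur$dy, theta = cur$theta,
                 center = ctr_global)
  attr(out, "score") <- best_score
  out
}

#' Align a serial-section stack to a reference section
#'
#' Chains pairwise alignments of consecutive sections ([align_pair()])
#' outward from the reference, composing them so that
#' `transforms[[k]]` maps section `k` onto the reference frame
#' (`transforms[[reference]]` is the identity). Composition is
#' `later_pair %after% earlier_pair`, i.e. section k is first mapped onto
#' its neighbor toward the reference, then by that neighbor's own chain.
#'
#' @param stack a [section_stack()]; multichannel stacks are aligned on
#'   channel 1.
#' @param reference index of the reference section (default: middle).
#' @param roi optional `c(y0, x0, height, width)` crop for matching.
#' @param max_rotation_deg,rotation_step_deg,refine_iter passed to
#'   [align_pair()].
#' @return list of [rigid2d()], one per section, relative to the reference.
#' @export
align_stack <- function(stack, reference = NULL, roi = NULL,
                        max_rotation_deg = 5, rotation_step_deg = 0.25,
                        refine_iter = 5L) {
  stopifnot(inherits(stack, "section_stack"))
  n <- length(stack)
  if (is.null(reference)) reference <- (n + 1) %/% 2
  if (reference < 1 || reference > n)
    stop("reference section out of range", call. = FALSE)
  ch1 <- function(k) {
    s <- stack$sections[[k]]
    if (length(dim(s)) == 3) s[, , 1] else s
  }
  out <- vector("list", n)
  ident_center <- if (is.null(roi))
    c((nrow(ch1(1)) + 1) / 2, (ncol(ch1(1)) + 1) / 2)
  else c(roi[1] + (roi[3] - 1) / 2, roi[2] + (roi[4] - 1) / 2)
  out[[reference]] <- rigid2d(0, 0, 0, center = ident_center)
  if (reference < n) for (k in (reference + 1):n) {
    pk <- tryCatch(
      align_pair(ch1(k - 1), ch1(k), max_rotation_deg, roi, rotation_step_deg,
                 refine_iter),
      error = function(e) stop(sprintf("alignment failed for pair (%d, %d): %s",
                                       k - 1, k, conditionMessage(e)),
                               call. = FALSE))
    out[[k]] <- compose_rigid2d(out[[k - 1]], pk)
  }
  if (reference > 1) for (k in (reference - 1):1) {
    pk <- tryCatch(
      align_pair(ch1(k + 1), ch1(k), max_rotation_deg, roi, rotation_step_deg,
                 refine_iter),
      error = function(e) stop(sprintf("alignment failed for pair (%d, %d): %s",
                                       k + 1, k, conditionMessage(e)),
                               call. = FALSE))
    out[[k]] <- compose_rigid2d(out[[k + 1]], pk)
  }
  out
}

#' Apply per-section transforms to a stack
#'
#' @param stack a [section_stack()].
#' @param transforms list of [rigid2d()], one per section (e.g. from
#'   [align_stack()] or a phantom's ground-truth table).
#' @param interpolation `"linear"` for intensities, `"nearest"` for labels.
#' @return the resampled [section_stack()].
#' @export
apply_transforms <- function(stack, transforms,
                             interpolation = c("linear", "nearest")) {
  stopifnot(inherits(stack, "section_stack"))
  interpolation <- match.arg(interpolation)
  if (length(transforms) != length(stack))
    stop(sprintf("%d transforms for %d sections", length(transforms),
                 length(stack)), call. = FALSE)
  secs <- mapply(function(s, tf) {
    out <- apply_rigid2d(s, tf, interpolation)
    if (interpolation == "nearest" && is.integer(s)) storage.mode(out) <- "integer"
    out
  }, stack$sections, transforms, SIMPLIFY = FALSE)
  section_stack(secs, stack$pixel_size_xy, stack$section_thickness,
                stack$channel_names)
}

#' Convert transforms to / from the shared CSV table schema
#'
#' The transforms table (`section_index, dx_px, dy_px, theta_deg`) is
#' bit-compatible between phantom ground truth and registration estimates so
#' the two can be compared directly.
#'
#' @param transforms list of [rigid2d()].
#' @return data.frame with one row per section.
#' @export
transforms_to_table <- function(transforms) {
  data.frame(section_index = seq_along(transforms),
             dx_px = vapply(transforms, `[[`, 0, "dx"),
             dy_px = vapply(transforms, `[[`, 0, "dy"),
             theta_deg = vapply(transforms, `[[`, 0, "theta"))
}

#' @rdname transforms_to_table
#' @param table a data.frame in the transforms schema.
#' @param center `(y, x)` rotation center to attach, 1-based pixels.
#' @export
table_to_transforms <- function(table, center = c(0, 0)) {
  lapply(seq_len(nrow(table)), function(i)
    rigid2d(table$dx_px[i], table$dy_px[i], table$theta_deg[i], center))
}
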