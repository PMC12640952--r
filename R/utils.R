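# Internal helpers shared across modules.

`%||%` <- function(a, b) if (is.null(a)) b else a

stopf <- function(fmt, ...) stop(sprintf(fmt, ...), call. = FALSE)

#' Trapezoidal integral
#' @param x,y numeric vectors of equal length; `x` strictly increasing.
#' @return scalar integral of y over x.
#' @keywords internal
#' @noRd
trapz <- function(x, y) {
  n <- length(x)
  if (n < 2L) return(0)
  sum(diff(x) * (y[-n] + y[-1L]) / 2)
}

# Circular (wrap-around) shift of a 3D array by integer offsets.
circ_shift3 <- function(a, s) {
  d <- dim(a)
  idx <- lapply(seq_len(3L), function(k) {
    sk <- s[k] %% d[k]
    if (sk == 0L) seq_len(d[k]) else c((d[k] - sk + 1L):d[k], seq_len(d[k] - sk))
  })
  a[idx[[1L]], idx[[2L]], idx[[3L]], drop = FALSE]
}

# 26-connected component labelling of a logical 3D mask.
# Iterative minimum-label propagation; adequate for the volume sizes used here.
connected_components3 <- function(mask) {
  d <- dim(mask)
  lab <- array(NA_integer_, d)
  lab[mask] <- seq_len(sum(mask))
  offs <- as.matrix(expand.grid(dx = -1:1, dy = -1:1, dz = -1:1))
  offs <- offs[rowSums(abs(offs)) > 0L, , drop = FALSE]
  pad <- function(a, s) {
    # shift with NA fill (non-circular)
    out <- array(NA_integer_, d)
    src <- lapply(1:3, function(k) {
      i <- seq_len(d[k]) - s[k]
      i[i < 1L | i > d[k]] <- NA_integer_
      i
    })
    ok <- lapply(src, function(i) which(!is.na(i)))
    out[ok[[1]], ok[[2]], ok[[3]]] <- a[src[[1]][ok[[1]]], src[[2]][ok[[2]]], src[[3]][ok[[3]]]]
    out
  }
  repeat {
    changed <- FALSE
    for (r in seq_len(nrow(offs))) {
      nb <- pad(lab, offs[r, ])
      upd <- mask & !is.na(nb) & (is.na(lab) | nb < lab)
      if (any(upd)) {
        lab[upd] <- nb[upd]
        changed <- TRUE
      }
    }
    if (!changed) break
  }
  # compact labels to 1..k
  u <- sort(unique(lab[mask]))
  lab[mask] <- match(lab[mask], u)
  lab
}

# Box-mean smoothing of a 3D array (window 3x3x3 truncated at edges).
box_smooth3 <- function(a) {
  d <- dim(a)
  acc <- array(0, d)
  cnt <- array(0, d)
  for (dx in -1:1) for (dy in -1:1) for (dz in -1:1) {
    xs <- seq_len(d[1]); ys <- seq_len(d[2]); zs <- seq_len(d[3])
    xs2 <- xs + dx; ys2 <- ys + dy; zs2 <- zs + dz
    okx <- xs2 >= 1 & xs2 <= d[1]; oky <- ys2 >= 1 & ys2 <= d[2]; okz <- zs2 >= 1 & zs2 <= d[3]
    acc[xs[okx], ys[oky], zs[okz]] <- acc[xs[okx], ys[oky], zs[okz]] +
      a[xs2[okx], ys2[oky], zs2[okz]]
    cnt[xs[okx], ys[oky], zs[okz]] <- cnt[xs[okx], ys[oky], zs[okz]] + 1
  }
  acc / cnt
}

# Wrap angle (degrees) into [0, 360).
wrap_deg <- function(a) ((a %% 360) + 360) %% 360
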