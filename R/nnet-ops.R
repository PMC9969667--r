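## Low-level network operations. Feature maps are (H*W) x C matrices in the
## column-major pixel order of an H x W grid (pixel index = (x-1)*H + y).
## 3x3 convolutions are computed as nine shifted matrix products, which keeps
## everything inside BLAS; spatial index tables are cached per grid size.

.opCache <- new.env(parent = emptyenv())

## nine zero-padded shift index vectors for a H x W grid, enumerated in the
## kernel-tap order k = (j-1)*3 + i with dy = i-2, dx = j-2
.shiftTables <- function(H, W) {
  key <- sprintf("s_%d_%d", H, W)
  if (!is.null(.opCache[[key]])) return(.opCache[[key]])
  I <- matrix(seq_len(H * W), H, W)
  Ip <- matrix(NA_integer_, H + 2L, W + 2L)
  Ip[2:(H + 1L), 2:(W + 1L)] <- I
  tabs <- vector("list", 9L)
  k <- 0L
  for (dx in -1:1) for (dy in -1:1) {
    k <- k + 1L
    idx <- as.vector(Ip[(1:H) + 1L + dy, (1:W) + 1L + dx])
    tabs[[k]] <- list(idx = idx, na = which(is.na(idx)))
  }
  .opCache[[key]] <- tabs
  tabs
}

## 2x2 max-pool index tables (H, W even)
.poolTables <- function(H, W) {
  key <- sprintf("p_%d_%d", H, W)
  if (!is.null(.opCache[[key]])) return(.opCache[[key]])
  I <- matrix(seq_len(H * W), H, W)
  ro <- seq(1L, H, 2L); co <- seq(1L, W, 2L)
  tabs <- list(as.vector(I[ro, co]),     as.vector(I[ro + 1L, co]),
               as.vector(I[ro, co + 1L]), as.vector(I[ro + 1L, co + 1L]))
  .opCache[[key]] <- tabs
  tabs
}

## nearest-neighbour 2x upsample index (maps output pixel -> input pixel)
.upTables <- function(Hin, Win) {
  key <- sprintf("u_%d_%d", Hin, Win)
  if (!is.null(.opCache[[key]])) return(.opCache[[key]])
  I <- matrix(seq_len(Hin * Win), Hin, Win)
  idx <- as.vector(I[rep(seq_len(Hin), each = 2L), rep(seq_len(Win), each = 2L)])
  .opCache[[key]] <- idx
  idx
}

.shiftMat <- function(X, tab) {
  S <- X[tab$idx, , drop = FALSE]
  if (length(tab$na) > 0L) S[tab$na, ] <- 0
  S
}

## kernel-tap order is symmetric: tap k reversed is tap 10-k
.convFwd <- function(layer, X, tabs) {
  n <- nrow(X)
  out <- matrix(layer$b, n, length(layer$b), byrow = TRUE)
  for (k in 1:9)
    out <- out + .shiftMat(X, tabs[[k]]) %*% layer$k[[k]]
  out
}

## returns list(dX, grad = list(k = ..., b = ...))
.convBwd <- function(layer, X, dY, tabs) {
  Cin <- ncol(X)
  dX <- matrix(0, nrow(X), Cin)
  gk <- vector("list", 9L)
  for (k in 1:9) {
    S <- .shiftMat(X, tabs[[k]])
    gk[[k]] <- crossprod(S, dY)
    dX <- dX + .shiftMat(dY %*% t(layer$k[[k]]), tabs[[10L - k]])
  }
  list(dX = dX, grad = list(k = gk, b = colSums(dY)))
}

.poolFwd <- function(X, tabs) {
  a1 <- X[tabs[[1L]], , drop = FALSE]; a2 <- X[tabs[[2L]], , drop = FALSE]
  a3 <- X[tabs[[3L]], , drop = FALSE]; a4 <- X[tabs[[4L]], , drop = FALSE]
  m <- pmax(a1, a2, a3, a4)
  sel <- matrix(4L, nrow(m), ncol(m))   # first-max tie break, tap order
  sel[a3 == m] <- 3L
  sel[a2 == m] <- 2L
  sel[a1 == m] <- 1L
  list(out = m, sel = sel)
}

.poolBwd <- function(dY, sel, tabs, nIn, C) {
  dX <- matrix(0, nIn, C)
  for (k in 1:4) {
    mk <- sel == k
    if (!any(mk)) next
    ## scatter: rows of dY where tap k won go to input index tabs[[k]]
    w <- which(mk)                       # linear indices in (nOut x C)
    r <- ((w - 1L) %% nrow(dY)) + 1L     # output pixel
    cc <- ((w - 1L) %/% nrow(dY)) + 1L   # channel
    dX[cbind(tabs[[k]][r], cc)] <- dX[cbind(tabs[[k]][r], cc)] + dY[w]
  }
  dX
}

.upFwd <- function(X, idx) X[idx, , drop = FALSE]

.upBwd <- function(dY, idx) {
  g <- rowsum(dY, group = idx)
  g[order(as.integer(rownames(g))), , drop = FALSE]
}

.relu <- function(X) { X[X < 0] <- 0; X }

.sigmoid <- function(x) 1 / (1 + exp(-x))

## ---- parameter-tree utilities ---------------------------------------------

## apply f to every numeric leaf of a parameter tree
.mapParams <- function(p, f) rapply(p, f, how = "replace")

## elementwise combination of two structurally identical trees
.map2Params <- function(a, b, f) {
  if (is.list(a)) {
    if (!is.list(b) || length(a) != length(b))
      stop("parameter structures do not match", call. = FALSE)
    out <- mapply(.map2Params, a, b, MoreArgs = list(f = f), SIMPLIFY = FALSE)
    names(out) <- names(a)
    return(out)
  }
  if (length(a) != length(b))
    stop("parameter structures do not match", call. = FALSE)
  f(a, b)
}

.sumSqParams <- function(p) sum(rapply(p, function(x) sum(x^2), how = "unlist"))
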