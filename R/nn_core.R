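# Self-contained CPU neural-network core: tensors are R arrays (H, W, C, N),
# convolutions run through the package's RcppArmadillo kernels, and every
# layer has an explicit forward and backward. Only what the segmenter and
# critic need is implemented.

heInit <- function(dims, fanIn) array(stats::rnorm(prod(dims), 0, sqrt(2 / fanIn)), dims)

makeConvParams <- function(k, cin, cout)
  list(w = heInit(c(k, k, cin, cout), k * k * cin), b = numeric(cout))

# ---- elementwise activations ------------------------------------------------

reluFwd <- function(x) { y <- x; y[x < 0] <- 0; y }
reluBwd <- function(x, dy) { dy[x < 0] <- 0; dy }

lreluFwd <- function(x, slope) { y <- x; neg <- x < 0; y[neg] <- slope * x[neg]; y }
lreluBwd <- function(x, dy, slope) { neg <- x < 0; dy[neg] <- slope * dy[neg]; dy }

sigmoidFwd <- function(x) 1 / (1 + exp(-x))
sigmoidBwdFromY <- function(y, dy) dy * y * (1 - y)

# ---- channel broadcast helpers ----------------------------------------------

bcC <- function(x, v) {
  # multiply/add helper: broadcast length-C vector over (H, W, C, N)
  rep(v, each = prod(dim(x)[1:2]))
}

perChannelMean <- function(x) {
  d <- dim(x)
  xp <- matrix(aperm(x, c(1, 2, 4, 3)), ncol = d[3])
  colMeans(xp)
}

perChannelMeanOf <- function(a, b) {
  d <- dim(a)
  xp <- matrix(aperm(a * b, c(1, 2, 4, 3)), ncol = d[3])
  colMeans(xp)
}

# ---- batch normalization ----------------------------------------------------

bnFwd <- function(x, g, b, run, train, momentum = 0.1, eps = 1e-5) {
  if (train) {
    mu <- perChannelMean(x)
    varc <- perChannelMeanOf(x, x) - mu^2
    run$mean <- (1 - momentum) * run$mean + momentum * mu
    run$var <- (1 - momentum) * run$var + momentum * varc
  } else {
    mu <- run$mean; varc <- run$var
  }
  istd <- 1 / sqrt(varc + eps)
  xhat <- (x - bcC(x, mu)) * bcC(x, istd)
  y <- xhat * bcC(x, g) + bcC(x, b)
  list(y = y, cache = list(xhat = xhat, istd = istd, g = g), run = run)
}

bnBwd <- function(cache, dy) {
  xhat <- cache$xhat
  dg <- perChannelMeanOf(dy, xhat) * prod(dim(dy)[c(1, 2, 4)])
  db <- perChannelMean(dy) * prod(dim(dy)[c(1, 2, 4)])
  mdy <- perChannelMean(dy)
  mdyx <- perChannelMeanOf(dy, xhat)
  dx <- bcC(dy, cache$g * cache$istd) *
    (dy - bcC(dy, mdy) - xhat * bcC(dy, mdyx))
  list(dx = dx, dg = dg, db = db)
}

newBnRun <- function(c) list(mean = numeric(c), var = rep(1, c))

# ---- squeeze-and-excitation gate --------------------------------------------

seFwd <- function(x, w1, b1, w2, b2) {
  d <- dim(x); hw <- d[1] * d[2]
  z <- colMeans(array(x, c(hw, d[3], d[4])))            # (C, N)
  if (is.null(dim(z))) z <- matrix(z, d[3], d[4])
  a <- w1 %*% z + b1
  aMask <- a > 0
  a[!aMask] <- 0
  g <- sigmoidFwd(w2 %*% a + b2)                        # (C, N), in (0, 1)
  y <- x * rep(g, each = hw)
  list(y = y, cache = list(x = x, z = z, a = a, aMask = aMask, g = g))
}

seBwd <- function(cache, dy, w1, w2) {
  x <- cache$x; d <- dim(x); hw <- d[1] * d[2]
  dgate <- colSums(array(x * dy, c(hw, d[3], d[4])))    # (C, N)
  if (is.null(dim(dgate))) dgate <- matrix(dgate, d[3], d[4])
  dx <- dy * rep(cache$g, each = hw)
  ds <- dgate * cache$g * (1 - cache$g)
  dw2 <- ds %*% t(cache$a); db2 <- rowSums(ds)
  da <- t(w2) %*% ds
  da[!cache$aMask] <- 0
  dw1 <- da %*% t(cache$z); db1 <- rowSums(da)
  dz <- t(w1) %*% da                                    # (C, N)
  dx <- dx + array(rep(dz / hw, each = hw), d)
  list(dx = dx, dw1 = dw1, db1 = db1, dw2 = dw2, db2 = db2)
}

# ---- channel concatenation --------------------------------------------------

ccat <- function(a, b) {
  da <- dim(a); db <- dim(b)
  out <- array(0, c(da[1], da[2], da[3] + db[3], da[4]))
  out[, , seq_len(da[3]), ] <- a
  out[, , da[3] + seq_len(db[3]), ] <- b
  out
}

csplit <- function(d, ca) {
  list(a = d[, , seq_len(ca), , drop = FALSE],
       b = d[, , -seq_len(ca), , drop = FALSE])
}

# ---- residual units ---------------------------------------------------------

makeUnitParams <- function(cin, cout, variant) {
  p <- list()
  bn1c <- if (variant == 1L) cin else cout
  p$conv1 <- makeConvParams(3L, cin, cout)
  p$conv2 <- makeConvParams(3L, cout, cout)
  p$bn1 <- list(g = rep(1, bn1c), b = numeric(bn1c))
  p$bn2 <- list(g = rep(1, cout), b = numeric(cout))
  if (cin != cout) p$proj <- makeConvParams(1L, cin, cout)
  p
}

unitFwd <- function(x, p, run, variant, train) {
  cache <- list(x = x, variant = variant)
  if (variant == 1L) {
    b1 <- bnFwd(x, p$bn1$g, p$bn1$b, run$bn1, train); run$bn1 <- b1$run
    r1 <- reluFwd(b1$y)
    c1 <- .conv2dFwd(r1, p$conv1$w, p$conv1$b, 1L, 1L)
    b2 <- bnFwd(c1, p$bn2$g, p$bn2$b, run$bn2, train); run$bn2 <- b2$run
    r2 <- reluFwd(b2$y)
    c2 <- .conv2dFwd(r2, p$conv2$w, p$conv2$b, 1L, 1L)
    s <- if (!is.null(p$proj)) .conv2dFwd(x, p$proj$w, p$proj$b, 1L, 0L) else x
    y <- c2 + s
    cache <- c(cache, list(b1 = b1$cache, b1y = b1$y, r1 = r1, b2 = b2$cache,
                           b2y = b2$y, r2 = r2))
  } else {
    c1 <- .conv2dFwd(x, p$conv1$w, p$conv1$b, 1L, 1L)
    b1 <- bnFwd(c1, p$bn1$g, p$bn1$b, run$bn1, train); run$bn1 <- b1$run
    r1 <- reluFwd(b1$y)
    c2 <- .conv2dFwd(r1, p$conv2$w, p$conv2$b, 1L, 1L)
    b2 <- bnFwd(c2, p$bn2$g, p$bn2$b, run$bn2, train); run$bn2 <- b2$run
    s <- if (!is.null(p$proj)) .conv2dFwd(x, p$proj$w, p$proj$b, 1L, 0L) else x
    pre <- b2$y + s
    y <- if (variant == 2L) reluFwd(pre) else pre
    cache <- c(cache, list(c1 = c1, b1 = b1$cache, b1y = b1$y, r1 = r1,
                           b2 = b2$cache, pre = pre))
  }
  list(y = y, cache = cache, run = run)
}

unitBwd <- function(cache, dy, p) {
  variant <- cache$variant
  x <- cache$x
  g <- list()
  if (variant == 1L) {
    dc2 <- dy
    bw2 <- .conv2dBwd(cache$r2, p$conv2$w, dc2, 1L, 1L, TRUE)
    g$conv2 <- list(w = bw2$dw, b = bw2$db)
    dr2 <- reluBwd(cache$b2y, bw2$dx)
    bb2 <- bnBwd(cache$b2, dr2)
    g$bn2 <- list(g = bb2$dg, b = bb2$db)
    bw1 <- .conv2dBwd(cache$r1, p$conv1$w, bb2$dx, 1L, 1L, TRUE)
    g$conv1 <- list(w = bw1$dw, b = bw1$db)
    dr1 <- reluBwd(cache$b1y, bw1$dx)
    bb1 <- bnBwd(cache$b1, dr1)
    g$bn1 <- list(g = bb1$dg, b = bb1$db)
    dx <- bb1$dx
    if (!is.null(p$proj)) {
      bwp <- .conv2dBwd(x, p$proj$w, dy, 1L, 0L, TRUE)
      g$proj <- list(w = bwp$dw, b = bwp$db)
      dx <- dx + bwp$dx
    } else dx <- dx + dy
  } else {
    dpre <- if (variant == 2L) reluBwd(cache$pre, dy) else dy
    bb2 <- bnBwd(cache$b2, dpre)
    g$bn2 <- list(g = bb2$dg, b = bb2$db)
    bw2 <- .conv2dBwd(cache$r1, p$conv2$w, bb2$dx, 1L, 1L, TRUE)
    g$conv2 <- list(w = bw2$dw, b = bw2$db)
    dr1 <- reluBwd(cache$b1y, bw2$dx)
    bb1 <- bnBwd(cache$b1, dr1)
    g$bn1 <- list(g = bb1$dg, b = bb1$db)
    bw1 <- .conv2dBwd(x, p$conv1$w, bb1$dx, 1L, 1L, TRUE)
    g$conv1 <- list(w = bw1$dw, b = bw1$db)
    dx <- bw1$dx
    if (!is.null(p$proj)) {
      bwp <- .conv2dBwd(x, p$proj$w, dpre, 1L, 0L, TRUE)
      g$proj <- list(w = bwp$dw, b = bwp$db)
      dx <- dx + bwp$dx
    } else dx <- dx + dpre
  }
  list(dx = dx, grads = g)
}

# ---- Adam -------------------------------------------------------------------

# Flatten nested grad/param lists (unit -> layer -> w/b) into named numeric
# leaves so the optimizer can walk them uniformly.
flattenLeaves <- function(x, prefix = "") {
  out <- list()
  for (n in names(x)) {
    key <- if (prefix == "") n else paste(prefix, n, sep = ".")
    if (is.list(x[[n]])) out <- c(out, flattenLeaves(x[[n]], key))
    else out[[key]] <- x[[n]]
  }
  out
}

assignLeaf <- function(x, path, value) {
  rec <- function(node, parts) {
    if (length(parts) == 1L) { node[[parts]] <- value; return(node) }
    node[[parts[1]]] <- rec(node[[parts[1]]], parts[-1])
    node
  }
  rec(x, strsplit(path, ".", fixed = TRUE)[[1]])
}

adamInit <- function() list(m = list(), v = list(), t = 0L)

adamStep <- function(params, grads, opt, lr, beta1 = 0.5, beta2 = 0.999,
                     eps = 1e-8, maximize = FALSE) {
  opt$t <- opt$t + 1L
  gf <- flattenLeaves(grads)
  for (k in names(gf)) {
    g <- gf[[k]]
    if (maximize) g <- -g
    m <- if (is.null(opt$m[[k]])) g * 0 else opt$m[[k]]
    v <- if (is.null(opt$v[[k]])) g * 0 else opt$v[[k]]
    m <- beta1 * m + (1 - beta1) * g
    v <- beta2 * v + (1 - beta2) * g^2
    opt$m[[k]] <- m; opt$v[[k]] <- v
    mh <- m / (1 - beta1^opt$t)
    vh <- v / (1 - beta2^opt$t)
    step <- lr * mh / (sqrt(vh) + eps)
    params <- assignLeaf(params, k, getLeaf(params, k) - step)
  }
  list(params = params, opt = opt)
}

getLeaf <- function(x, path) {
  for (p in strsplit(path, ".", fixed = TRUE)[[1]]) x <- x[[p]]
  x
}

# elementwise sum of two nested grad lists (same structure or missing parts)
addGrads <- function(a, b) {
  if (is.null(a)) return(b)
  if (is.null(b)) return(a)
  if (!is.list(a)) return(a + b)
  for (n in union(names(a), names(b))) a[[n]] <- addGrads(a[[n]], b[[n]])
  a
}
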