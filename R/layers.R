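# Internal tensor plumbing for the feature extractor and heads.
#
# Activations travel as 5-d arrays (H, W, D, N, C); 2-d images use D = 1.
# All backward passes are hand-derived; convolution and pooling kernels live
# in src/conv.cpp.

# Stack a list of images (or a single image) into a (H, W, D, N, 1) batch.
stackImages <- function(images) {
  if (!is.list(images)) images <- list(images)
  d <- dim(images[[1L]])
  if (length(d) == 2L) d <- c(d, 1L)
  n <- length(images)
  x <- array(0, c(d, n, 1L))
  for (i in seq_len(n)) x[, , , i, 1L] <- images[[i]]
  x
}

# ---- feature extractor ----------------------------------------------------

# Channel plan: double from nFiltersStart for the first three stacks, then
# stay constant (16/32/64/64 for the reference 3-d configuration).
channelPlan <- function(arch) {
  s <- seq_len(arch@nStacks)
  as.integer(arch@nFiltersStart * 2^pmin(s - 1L, 2L))
}

archDims <- function(arch) {
  nd <- length(arch@inputShape)
  shape3 <- if (nd == 2L) c(arch@inputShape, 1L) else arch@inputShape
  kdim <- if (nd == 2L) c(arch@kernelSize, arch@kernelSize, 1L)
          else rep(arch@kernelSize, 3L)
  pdim <- if (nd == 2L) c(arch@poolSize, arch@poolSize, 1L)
          else rep(arch@poolSize, 3L)
  list(shape3 = as.integer(shape3), kdim = as.integer(kdim),
       pdim = as.integer(pdim))
}

#' Width of the flattened feature vector
#'
#' @param arch an [ArchitectureSpec].
#' @return integer: (spatial size after pooling) x (last channel count).
#' @examples
#' featureWidth(cfnetArchitecture(c(64, 64, 64)))  # 4096
#' @export
featureWidth <- function(arch) {
  d <- archDims(arch)
  outSpatial <- d$shape3
  for (s in seq_len(arch@nStacks)) outSpatial <- outSpatial %/% d$pdim
  plan <- channelPlan(arch)
  as.integer(prod(outSpatial) * plan[length(plan)])
}

feForward <- function(model, x, train, updateBuffers = FALSE,
                      momentum = 0.1, eps = 1e-5) {
  arch <- model@arch
  d <- archDims(arch)
  fe <- model@thetaFE
  buf <- model@buffers
  caches <- vector("list", arch@nStacks)
  for (s in seq_len(arch@nStacks)) {
    convIn <- x
    a <- .convForward(x, dim(x), fe[[nm("conv", s, "W")]],
                      fe[[nm("conv", s, "b")]], d$kdim)
    rb <- .reluBnForward(a, dim(a), fe[[nm("bn", s, "gamma")]],
                         fe[[nm("bn", s, "beta")]],
                         buf[[nm("bn", s, "mean")]],
                         buf[[nm("bn", s, "var")]], train, eps)
    if (train && updateBuffers) {
      v <- 1 / rb$istd^2 - eps
      buf[[nm("bn", s, "mean")]] <- (1 - momentum) *
        buf[[nm("bn", s, "mean")]] + momentum * rb$mu
      buf[[nm("bn", s, "var")]] <- (1 - momentum) *
        buf[[nm("bn", s, "var")]] + momentum * v
    }
    pl <- .poolForward(rb$y, dim(rb$y), d$pdim)
    caches[[s]] <- list(convIn = convIn, convInDim = dim(convIn),
                        r = rb$r, mu = rb$mu, istd = rb$istd,
                        train = train,
                        poolWhich = pl$which, poolInDim = dim(rb$y))
    x <- pl$y
  }
  dlast <- dim(x)
  n <- dlast[4L]
  ap <- aperm(x, c(1L, 2L, 3L, 5L, 4L))
  dim(ap) <- c(prod(dlast[c(1:3, 5L)]), n)
  list(F = t(ap), caches = caches, lastDim = dlast, buffers = buf)
}

feBackward <- function(model, fw, dF, needDx = FALSE) {
  arch <- model@arch
  d <- archDims(arch)
  fe <- model@thetaFE
  dlast <- fw$lastDim
  dx <- t(dF)
  dim(dx) <- c(dlast[1:3], dlast[5L], dlast[4L])
  dx <- aperm(dx, c(1L, 2L, 3L, 5L, 4L))
  grads <- list()
  for (s in rev(seq_len(arch@nStacks))) {
    cc <- fw$caches[[s]]
    dpool <- .poolBackward(dx, cc$poolWhich, prod(cc$poolInDim))
    dim(dpool) <- cc$poolInDim
    bb <- .reluBnBackward(dpool, cc$r, cc$poolInDim,
                          fe[[nm("bn", s, "gamma")]], cc$mu, cc$istd,
                          cc$train)
    grads[[nm("bn", s, "gamma")]] <- bb$dgamma
    grads[[nm("bn", s, "beta")]] <- bb$dbeta
    cb <- .convBackward(cc$convIn, cc$convInDim, fe[[nm("conv", s, "W")]],
                        d$kdim, bb$dx, s > 1L || needDx)
    grads[[nm("conv", s, "W")]] <- cb$dw
    grads[[nm("conv", s, "b")]] <- cb$db
    dx <- cb$dx
  }
  list(grads = grads, dx = dx)
}

nm <- function(kind, s, what) paste0(kind, s, ".", what)

# ---- two-layer fully connected heads --------------------------------------

headForward <- function(par, Fm) {
  n <- nrow(Fm)
  z1 <- Fm %*% par$W1 + rep(par$b1, each = n)
  mask <- z1 > 0
  a1 <- z1 * mask
  out <- a1 %*% par$W2 + rep(par$b2, each = n)
  list(out = out, cache = list(Fm = Fm, mask = mask, a1 = a1))
}

headBackward <- function(par, cache, dOut) {
  dW2 <- crossprod(cache$a1, dOut)
  db2 <- colSums(dOut)
  dz1 <- (dOut %*% t(par$W2)) * cache$mask
  dW1 <- crossprod(cache$Fm, dz1)
  db1 <- colSums(dz1)
  dF <- dz1 %*% t(par$W1)
  list(grads = list(W1 = dW1, b1 = db1, W2 = dW2, b2 = db2), dF = dF)
}

initHead <- function(fIn, hidden, kOut) {
  list(W1 = matrix(stats::rnorm(fIn * hidden, sd = sqrt(2 / fIn)),
                   fIn, hidden),
       b1 = numeric(hidden),
       W2 = matrix(stats::rnorm(hidden * kOut, sd = sqrt(1 / hidden)),
                   hidden, kOut),
       b2 = numeric(kOut))
}

# ---- Adam -----------------------------------------------------------------

adamInit <- function(params) {
  list(t = 0L,
       m = lapply(params, function(p) p * 0),
       v = lapply(params, function(p) p * 0))
}

adamStep <- function(params, grads, state, lr,
                     beta1 = 0.9, beta2 = 0.999, eps = 1e-8) {
  state$t <- state$t + 1L
  c1 <- 1 - beta1^state$t
  c2 <- 1 - beta2^state$t
  for (name in names(params)) {
    g <- grads[[name]]
    state$m[[name]] <- beta1 * state$m[[name]] + (1 - beta1) * g
    state$v[[name]] <- beta2 * state$v[[name]] + (1 - beta2) * g^2
    params[[name]] <- params[[name]] -
      lr * (state$m[[name]] / c1) / (sqrt(state$v[[name]] / c2) + eps)
  }
  list(params = params, state = state)
}

sigmoid <- function(x) 1 / (1 + exp(-x))
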