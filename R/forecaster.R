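#' Train the recurrent publication-dynamics forecaster
#'
#' Fits a compact encoder-decoder network of Gated Recurrent Units with an
#' additive attention layer over the encoder states, the architecture used to
#' forecast cumulative per-gene publication/citation series. Each series is
#' min-max scaled on its training window; the decoder is trained with teacher
#' forcing under an RMSprop optimiser with squared error on log1p-transformed
#' scaled values ("log error"). A `validation_fraction` of the series is held
#' out of training entirely.
#'
#' The default desk-scale configuration is one encoder and one decoder GRU
#' layer of 5 units; deeper stacks are available through `n_layers`.
#'
#' @param series A long series tibble (`gene`, `category`, `year`, `value`),
#'   e.g. from [assemble_series()] or [gen_timeseries()].
#' @param train_end Last training year; later years form the forecast
#'   horizon.
#' @param units GRU width (default 5).
#' @param n_layers Number of stacked GRU layers in encoder and decoder.
#' @param epochs Training epochs (full-batch).
#' @param lr RMSprop learning rate.
#' @param validation_fraction Fraction of series reserved for validation.
#' @param seed Integer seed; training is deterministic given it.
#' @return An object of class `genelit_forecaster` (parameters, per-series
#'   scalers, loss history, validation ids). Use [forecast_series()] to
#'   produce forecasts.
#' @export
train_forecaster <- function(series, train_end = 2013L, units = 5L,
                             n_layers = 1L, epochs = 250L, lr = 0.02,
                             validation_fraction = 0.3, seed = 1L) {
  prep <- prepare_series_matrix(series, train_end)
  if (nrow(prep$X) < 10) abort("need at least 10 series to train")
  if (ncol(prep$X) < 5) abort("training window must span at least 5 years")

  set.seed(seed)
  usable <- which(!prep$ids$degenerate)
  if (length(usable) < nrow(prep$ids)) {
    warn(paste0(nrow(prep$ids) - length(usable),
                " constant series excluded from the training loss"))
  }
  n_val <- floor(validation_fraction * length(usable))
  val <- sort(sample(usable, n_val))
  train <- setdiff(usable, val)

  p <- init_forecaster_params(units, n_layers)
  cache_sq <- lapply(p, function(m) m * 0)
  X <- prep$X[train, , drop = FALSE]
  Y <- prep$Y[train, , drop = FALSE]
  loss_hist <- numeric(epochs)
  for (ep in seq_len(epochs)) {
    fb <- forecaster_loss_grad(p, X, Y, teacher = TRUE)
    loss_hist[ep] <- fb$loss
    for (nm in names(p)) {
      g <- fb$grads[[nm]]
      cache_sq[[nm]] <- 0.9 * cache_sq[[nm]] + 0.1 * g^2
      p[[nm]] <- p[[nm]] - lr * g / (sqrt(cache_sq[[nm]]) + 1e-8)
    }
  }

  structure(list(
    params = p, units = units, n_layers = n_layers,
    years_train = prep$years_train, years_horizon = prep$years_horizon,
    train_end = train_end, ids = prep$ids, val_rows = val, train_rows = train,
    loss_history = loss_hist, seed = seed
  ), class = "genelit_forecaster")
}

#' Forecast series with a trained forecaster
#'
#' Free-running decoding: each decoder step receives the model's own previous
#' prediction. Outputs are inverse min-max scaled and clamped at zero.
#'
#' @param forecaster A `genelit_forecaster`.
#' @param series Optional long series tibble to forecast (defaults to the
#'   training input layout stored in the forecaster; must share its year
#'   grid).
#' @return A long tibble `gene`, `category`, `year`, `value`, `kind =
#'   "predicted"` over the horizon years.
#' @export
forecast_series <- function(forecaster, series) {
  prep <- prepare_series_matrix(series, forecaster$train_end)
  stopifnot(identical(prep$years_train, forecaster$years_train))
  P <- forecaster_decode(forecaster$params, prep$X,
                         horizon = length(prep$years_horizon))
  # inverse scaling
  rng <- prep$ids$max - prep$ids$min
  vals <- P * rng + prep$ids$min
  vals[prep$ids$degenerate, ] <- prep$ids$min[prep$ids$degenerate]
  vals <- pmax(vals, 0)
  out <- tidyr::expand_grid(
    i = seq_len(nrow(prep$ids)), j = seq_along(prep$years_horizon))
  tibble(gene = prep$ids$gene[out$i], category = prep$ids$category[out$i],
         year = prep$years_horizon[out$j],
         value = vals[cbind(out$i, out$j)], kind = "predicted")
}

prepare_series_matrix <- function(series, train_end) {
  series <- as_tibble(series)
  years <- sort(unique(series$year))
  years_train <- years[years <= train_end]
  years_horizon <- years[years > train_end]
  if (length(years_horizon) == 0) abort("no horizon years after train_end")
  wide <- series |>
    arrange(.data$gene, .data$category, .data$year) |>
    tidyr::pivot_wider(id_cols = c("gene", "category"),
                       names_from = "year", values_from = "value")
  mat <- as.matrix(wide[as.character(years)])
  if (anyNA(mat)) abort("series must cover the full year grid")
  Xr <- mat[, as.character(years_train), drop = FALSE]
  Yr <- mat[, as.character(years_horizon), drop = FALSE]
  mn <- apply(Xr, 1, min); mx <- apply(Xr, 1, max)
  degen <- mx == mn
  rng <- ifelse(degen, 1, mx - mn)
  X <- (Xr - mn) / rng
  Y <- (Yr - mn) / rng
  X[degen, ] <- 0; Y[degen, ] <- 0
  list(X = X, Y = Y,
       ids = tibble(gene = wide$gene, category = wide$category,
                    min = mn, max = mx, degenerate = degen),
       years_train = years_train, years_horizon = years_horizon)
}

init_forecaster_params <- function(units, n_layers) {
  K <- units
  p <- list()
  mk <- function(nr, nc) matrix(rnorm(nr * nc, sd = 0.25), nr, nc)
  for (l in seq_len(n_layers)) {
    din_e <- if (l == 1) 1L else K
    din_d <- if (l == 1) K + 1L else K
    for (g in c("z", "r", "h")) {
      p[[paste0("eW", g, l)]] <- mk(din_e, K)
      p[[paste0("eU", g, l)]] <- mk(K, K)
      p[[paste0("eb", g, l)]] <- matrix(0, 1, K)
      p[[paste0("dW", g, l)]] <- mk(din_d, K)
      p[[paste0("dU", g, l)]] <- mk(K, K)
      p[[paste0("db", g, l)]] <- matrix(0, 1, K)
    }
  }
  p$A1 <- mk(K, K); p$A2 <- mk(K, K)
  p$av <- mk(K, 1); p$ab <- matrix(0, 1, K)
  p$wo <- mk(K, 1); p$bo <- matrix(0, 1, 1)
  p
}

sigmoid <- function(x) 1 / (1 + exp(-x))
badd <- function(m, b) m + rep(b, each = nrow(m))  # add 1xK bias rowwise

gru_cell_fwd <- function(x, hprev, W, U, b) {
  z <- sigmoid(badd(x %*% W$z + hprev %*% U$z, b$z))
  r <- sigmoid(badd(x %*% W$r + hprev %*% U$r, b$r))
  hh <- tanh(badd(x %*% W$h + (r * hprev) %*% U$h, b$h))
  h <- (1 - z) * hprev + z * hh
  list(h = h, cache = list(x = x, hprev = hprev, z = z, r = r, hh = hh))
}

gru_cell_bwd <- function(dh, cache, W, U, grads, side, l) {
  key <- function(part) paste0(side, part, l)
  x <- cache$x; hprev <- cache$hprev
  z <- cache$z; r <- cache$r; hh <- cache$hh
  dz <- dh * (hh - hprev)
  dhh <- dh * z
  dhprev <- dh * (1 - z)
  dahh <- dhh * (1 - hh^2)
  grads[[key("Wh")]] <- grads[[key("Wh")]] + crossprod(x, dahh)
  grads[[key("Uh")]] <- grads[[key("Uh")]] + crossprod(r * hprev, dahh)
  grads[[key("bh")]] <- grads[[key("bh")]] + colSums(dahh)
  drh <- dahh %*% Matrix::t(U$h)
  dr <- drh * hprev
  dhprev <- dhprev + drh * r
  dx <- dahh %*% Matrix::t(W$h)
  daz <- dz * z * (1 - z)
  grads[[key("Wz")]] <- grads[[key("Wz")]] + crossprod(x, daz)
  grads[[key("Uz")]] <- grads[[key("Uz")]] + crossprod(hprev, daz)
  grads[[key("bz")]] <- grads[[key("bz")]] + colSums(daz)
  dhprev <- dhprev + daz %*% Matrix::t(U$z)
  dx <- dx + daz %*% Matrix::t(W$z)
  dar <- dr * r * (1 - r)
  grads[[key("Wr")]] <- grads[[key("Wr")]] + crossprod(x, dar)
  grads[[key("Ur")]] <- grads[[key("Ur")]] + crossprod(hprev, dar)
  grads[[key("br")]] <- grads[[key("br")]] + colSums(dar)
  dhprev <- dhprev + dar %*% Matrix::t(U$r)
  dx <- dx + dar %*% Matrix::t(W$r)
  list(dx = dx, dhprev = dhprev, grads = grads)
}

layer_params <- function(p, side, l) {
  list(W = list(z = p[[paste0(side, "Wz", l)]],
                r = p[[paste0(side, "Wr", l)]],
                h = p[[paste0(side, "Wh", l)]]),
       U = list(z = p[[paste0(side, "Uz", l)]],
                r = p[[paste0(side, "Ur", l)]],
                h = p[[paste0(side, "Uh", l)]]),
       b = list(z = p[[paste0(side, "bz", l)]],
                r = p[[paste0(side, "br", l)]],
                h = p[[paste0(side, "bh", l)]]))
}

n_layers_of <- function(p) {
  sum(grepl("^eWz", names(p)))
}

# Forward pass shared by training (teacher forcing) and decoding. Returns the
# full cache needed for backprop.
forecaster_fwd <- function(p, X, Y = NULL, horizon = NULL, teacher = TRUE) {
  B <- nrow(X); Tn <- ncol(X); K <- ncol(p$A1)
  L <- n_layers_of(p)
  H <- if (teacher) ncol(Y) else horizon

  enc_states <- vector("list", L)   # [[l]][[t]] cell outputs
  enc_caches <- vector("list", L)
  h <- lapply(seq_len(L), function(l) matrix(0, B, K))
  for (l in seq_len(L)) { enc_states[[l]] <- vector("list", Tn); enc_caches[[l]] <- vector("list", Tn) }
  for (t in seq_len(Tn)) {
    inp <- matrix(X[, t], B, 1)
    for (l in seq_len(L)) {
      lp <- layer_params(p, "e", l)
      st <- gru_cell_fwd(inp, h[[l]], lp$W, lp$U, lp$b)
      h[[l]] <- st$h
      enc_states[[l]][[t]] <- st$h
      enc_caches[[l]][[t]] <- st$cache
      inp <- st$h
    }
  }
  hT <- h[[L]]

  # additive attention over top-layer encoder states, query = final state
  tj <- vector("list", Tn)
  E <- matrix(0, B, Tn)
  for (t in seq_len(Tn)) {
    a <- badd(enc_states[[L]][[t]] %*% p$A1 + hT %*% p$A2, p$ab)
    tj[[t]] <- tanh(a)
    E[, t] <- tj[[t]] %*% p$av
  }
  Emax <- apply(E, 1, max)
  W <- exp(E - Emax)
  alpha <- W / rowSums(W)
  ctx <- matrix(0, B, K)
  for (t in seq_len(Tn)) ctx <- ctx + alpha[, t] * enc_states[[L]][[t]]

  # decoder, initial state = encoder final state at each layer
  s <- h
  dec_caches <- vector("list", L)
  for (l in seq_len(L)) dec_caches[[l]] <- vector("list", H)
  P <- matrix(0, B, H)
  s_top <- vector("list", H)
  yprev_used <- matrix(0, B, H)
  for (t in seq_len(H)) {
    yprev <- if (t == 1) X[, Tn] else if (teacher) Y[, t - 1] else P[, t - 1]
    yprev_used[, t] <- yprev
    inp <- cbind(yprev, ctx)
    for (l in seq_len(L)) {
      lp <- layer_params(p, "d", l)
      st <- gru_cell_fwd(inp, s[[l]], lp$W, lp$U, lp$b)
      s[[l]] <- st$h
      dec_caches[[l]][[t]] <- st$cache
      inp <- st$h
    }
    s_top[[t]] <- s[[L]]
    P[, t] <- s[[L]] %*% p$wo + p$bo[1, 1]
  }
  list(P = P, enc_states = enc_states, enc_caches = enc_caches,
       dec_caches = dec_caches, s_top = s_top, alpha = alpha, tj = tj,
       ctx = ctx, hT = hT, B = B, Tn = Tn, H = H, K = K, L = L)
}

forecaster_decode <- function(p, X, horizon) {
  forecaster_fwd(p, X, horizon = horizon, teacher = FALSE)$P
}

forecaster_loss_grad <- function(p, X, Y, teacher = TRUE) {
  fw <- forecaster_fwd(p, X, Y, teacher = teacher)
  B <- fw$B; Tn <- fw$Tn; H <- fw$H; K <- fw$K; L <- fw$L
  Pc <- pmax(fw$P, -0.9)
  resid <- log1p(Pc) - log1p(Y)
  loss <- mean(resid^2)
  dP <- 2 * resid / (1 + Pc) / (B * H)
  dP[fw$P < -0.9] <- 0

  grads <- lapply(p, function(m) m * 0)
  ds <- lapply(seq_len(L), function(l) matrix(0, B, K))
  dctx <- matrix(0, B, K)
  for (t in rev(seq_len(H))) {
    dtop <- dP[, t, drop = FALSE] %*% Matrix::t(p$wo)
    grads$wo <- grads$wo + crossprod(fw$s_top[[t]], dP[, t, drop = FALSE])
    grads$bo <- grads$bo + sum(dP[, t])
    ds[[L]] <- ds[[L]] + dtop
    dinp <- NULL
    for (l in rev(seq_len(L))) {
      lp <- layer_params(p, "d", l)
      dcur <- ds[[l]]
      if (!is.null(dinp)) dcur <- dcur + dinp
      bk <- gru_cell_bwd(dcur, fw$dec_caches[[l]][[t]], lp$W, lp$U,
                         grads, "d", l)
      grads <- bk$grads
      ds[[l]] <- bk$dhprev
      dinp <- bk$dx
    }
    # dinp is the gradient wrt cbind(yprev, ctx); yprev is teacher-forced data
    dctx <- dctx + dinp[, -1, drop = FALSE]
  }
  dhT_list <- ds  # decoder initial states were the encoder final states

  # attention backward
  dH_enc <- lapply(seq_len(Tn), function(t) matrix(0, B, K))
  dhT <- matrix(0, B, K)
  dalpha <- matrix(0, B, Tn)
  for (t in seq_len(Tn)) {
    dalpha[, t] <- rowSums(dctx * fw$enc_states[[L]][[t]])
    dH_enc[[t]] <- dH_enc[[t]] + fw$alpha[, t] * dctx
  }
  srow <- rowSums(fw$alpha * dalpha)
  dE <- fw$alpha * (dalpha - srow)
  for (t in seq_len(Tn)) {
    det <- dE[, t, drop = FALSE]
    dtj <- det %*% Matrix::t(p$av)
    grads$av <- grads$av + crossprod(fw$tj[[t]], det)
    da <- dtj * (1 - fw$tj[[t]]^2)
    grads$A1 <- grads$A1 + crossprod(fw$enc_states[[L]][[t]], da)
    grads$A2 <- grads$A2 + crossprod(fw$hT, da)
    grads$ab <- grads$ab + colSums(da)
    dH_enc[[t]] <- dH_enc[[t]] + da %*% Matrix::t(p$A1)
    dhT <- dhT + da %*% Matrix::t(p$A2)
  }

  # encoder backward through time, all layers; the top layer's state at every
  # step also feeds the attention, and the final states seeded the decoder
  dh <- dhT_list
  dh[[L]] <- dh[[L]] + dhT
  for (t in rev(seq_len(Tn))) {
    dinp <- NULL
    for (l in rev(seq_len(L))) {
      lp <- layer_params(p, "e", l)
      dcur <- dh[[l]]
      if (l == L) dcur <- dcur + dH_enc[[t]]
      if (!is.null(dinp)) dcur <- dcur + dinp
      bk <- gru_cell_bwd(dcur, fw$enc_caches[[l]][[t]], lp$W, lp$U,
                         grads, "e", l)
      grads <- bk$grads
      dh[[l]] <- bk$dhprev
      dinp <- bk$dx
    }
  }
  list(loss = loss, grads = grads)
}

#' @export
print.genelit_forecaster <- function(x, ...) {
  cat("<genelit_forecaster> ", x$n_layers, "x", x$units,
      "-unit GRU encoder-decoder with attention; trained ",
      length(x$loss_history), " epochs, final loss ",
      signif(last(x$loss_history), 4), "\n", sep = "")
  invisible(x)
}
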