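#' Peephole LSTM and CNN sequence classifiers
#'
#' The neural component scores a candidate from a token sequence derived
#' from the sentence (word sequence between the entities, or the shortest
#' dependency path in dependency or sentence order, optionally with POS
#' embeddings and entity-head generalization). The recurrent cell is a
#' peephole LSTM whose gates read the memory cell:
#' \deqn{i_t = \sigma(W^{(i)} x_t + U^{(i)} h_{t-1} + V^{(i)} c_{t-1} + b^{(i)})}
#' \deqn{f_t = \sigma(W^{(f)} x_t + U^{(f)} h_{t-1} + V^{(f)} c_{t-1} + b^{(f)})}
#' \deqn{c_t = f_t \odot c_{t-1} + i_t \odot \tanh(W^{(c)} x_t + U^{(c)} h_{t-1} + b^{(c)})}
#' \deqn{o_t = \sigma(W^{(o)} x_t + U^{(o)} h_{t-1} + V^{(o)} c_t + b^{(o)})}
#' \deqn{h_t = o_t \odot \tanh(c_t)}
#' (note the output gate peeks at the *current* cell). The final hidden state
#' feeds a logistic output layer. Peephole connections are diagonal
#' (elementwise vectors). All gradients are exact BPTT and are verified
#' against central finite differences in the test suite. A 1-D CNN with
#' max-over-time pooling is provided as a baseline encoder.
#'
#' @name neural_model
NULL

# ---- input encoding ----------------------------------------------------------

#' Parse an input-method string
#'
#' Accepts `"WORD"`, `"WORD-POS"`, `"HEAD"`, `"SDP-dep"`, `"SDP-seq"` and
#' `+POS` / `+HEAD` suffixes (e.g. `"SDP-seq+POS+HEAD"`).
#'
#' @param method Method string.
#' @return List with `base` (`"WORD"`, `"SDP-dep"` or `"SDP-seq"`),
#'   `use_pos`, `use_head`.
#' @export
parse_method <- function(method) {
  parts <- strsplit(method, "+", fixed = TRUE)[[1]]
  base <- parts[[1]]
  mods <- toupper(parts[-1])
  if (!all(mods %in% c("POS", "HEAD"))) stop("unknown method modifier in ", method)
  use_pos <- "POS" %in% mods
  use_head <- "HEAD" %in% mods
  if (base == "WORD-POS") { base <- "WORD"; use_pos <- TRUE }
  if (base == "HEAD") { base <- "WORD"; use_head <- TRUE }
  if (!base %in% c("WORD", "SDP-dep", "SDP-seq")) stop("unknown input method ", method)
  list(base = base, use_pos = use_pos, use_head = use_head)
}

#' Encode a candidate as a token/relation sequence
#'
#' `WORD` takes the tokens from the chemical to the disease mention
#' (inclusive of both mentions by default); the `HEAD` variant replaces each
#' entity's tokens by its syntactic head. `SDP-dep`/`SDP-seq` embed the
#' shortest-dependency-path sequence ([sdp_sequence()]); with the `HEAD`
#' modifier the two endpoint words are replaced by `<chemical>`/`<disease>`
#' type placeholders (the endpoints are already the entity heads, so the
#' placeholder is what generalizes across entity names).
#'
#' @param sentence A `cdr_sentence`.
#' @param candidate One-row candidate tibble.
#' @param method Input method string (see [parse_method()]).
#' @param include_entities Include the entity tokens themselves in `WORD`
#'   sequences (default `TRUE`).
#' @return Tibble with columns `kind` (`word`/`relation`), `label` and `pos`
#'   (`NA` for relations). Errors with class `cdr_no_path` when an SDP view
#'   is unavailable.
#' @export
encode_input <- function(sentence, candidate, method = "SDP-seq+POS+HEAD",
                         include_entities = TRUE) {
  m <- parse_method(method)
  cs <- c(candidate$chem_start, candidate$chem_end)
  ds <- c(candidate$dis_start, candidate$dis_end)
  toks <- sentence$tokens
  if (m$base == "WORD") {
    lo <- min(cs[1], ds[1]); hi <- max(cs[2], ds[2]) - 1L
    idx <- lo:hi
    if (!include_entities) {
      idx <- setdiff(idx, c(cs[1]:(cs[2] - 1L), ds[1]:(ds[2] - 1L)))
    }
    if (m$use_head) {
      hc <- entity_head(cs[1], cs[2], sentence)
      hd <- entity_head(ds[1], ds[2], sentence)
      idx <- idx[!(idx %in% setdiff(c(cs[1]:(cs[2] - 1L), ds[1]:(ds[2] - 1L)), c(hc, hd)))]
    }
    if (length(idx) == 0L) idx <- c(cs[1], ds[1])
    tibble(kind = "word",
           label = tolower(toks$surface[match(idx, toks$index)]),
           pos = toks$pos[match(idx, toks$index)])
  } else {
    hc <- entity_head(cs[1], cs[2], sentence)
    hd <- entity_head(ds[1], ds[2], sentence)
    mode <- if (m$base == "SDP-dep") "dep" else "seq"
    s <- sdp_sequence(sentence, hc, hd, mode)
    lab <- ifelse(s$kind == "word", tolower(s$label), s$label)
    if (m$use_head) {
      lab[s$kind == "word" & s$token_index == hc] <- "<chemical>"
      lab[s$kind == "word" & s$token_index == hd] <- "<disease>"
    }
    tibble(kind = s$kind, label = lab,
           pos = ifelse(s$kind == "word",
                        toks$pos[match(s$token_index, toks$index)], NA_character_))
  }
}

# ---- vocabularies and embeddings --------------------------------------------

UNK <- "<unk>"

#' Build embedding vocabularies from training sequences
#'
#' @param sequences List of tibbles from [encode_input()].
#' @return List of character vectors `word`, `rel`, `pos`, each starting with
#'   the `<unk>` entry (words also include the `<chemical>`/`<disease>`
#'   placeholders and POS the `<none>` tag used for relation elements).
#' @export
build_vocabs <- function(sequences) {
  all_rows <- bind_rows(sequences)
  list(
    word = c(UNK, "<chemical>", "<disease>",
             sort(unique(all_rows$label[all_rows$kind == "word"]))),
    rel = c(UNK, sort(unique(all_rows$label[all_rows$kind == "relation"]))),
    pos = c(UNK, "<none>", sort(unique(all_rows$pos[!is.na(all_rows$pos)]))))
}

seq_to_ids <- function(seq_tbl, vocabs) {
  type <- ifelse(seq_tbl$kind == "word", 1L, 2L)
  id <- integer(nrow(seq_tbl))
  id[type == 1L] <- match(seq_tbl$label[type == 1L], vocabs$word, nomatch = 1L)
  id[type == 2L] <- match(seq_tbl$label[type == 2L], vocabs$rel, nomatch = 1L)
  pos_id <- match(ifelse(is.na(seq_tbl$pos), "<none>", seq_tbl$pos),
                  vocabs$pos, nomatch = 1L)
  list(type = type, id = id, pos_id = pos_id)
}

#' Read a plain-text word-embedding table
#'
#' Whitespace-separated `word v1 ... vd` lines.
#'
#' @param path File path.
#' @return List with `words` (character) and `vectors` (matrix, one row per
#'   word).
#' @export
read_embeddings <- function(path) {
  lines <- readLines(path, warn = FALSE)
  lines <- lines[nzchar(trimws(lines))]
  parts <- strsplit(trimws(lines), "[ \t]+")
  d <- length(parts[[1]]) - 1L
  if (d < 1L || !all(vapply(parts, length, integer(1)) == d + 1L)) {
    stop("embedding file rows have inconsistent dimensions")
  }
  list(words = vapply(parts, `[`, "", 1L),
       vectors = do.call(rbind, lapply(parts, function(p) as.numeric(p[-1L]))))
}

rand_mat <- function(nr, nc, scale = 0.1) {
  matrix(stats::runif(nr * nc, -scale, scale), nr, nc)
}

#' Initialize a neural candidate classifier
#'
#' @param vocabs From [build_vocabs()].
#' @param method Input method string; decides whether POS embeddings exist
#'   and which sequences the model expects.
#' @param d Embedding dimension (default 200, the usual pretrained width).
#' @param hidden LSTM hidden size `H` (default 100).
#' @param arch `"lstm"` or `"cnn"`.
#' @param n_maps CNN feature maps (default 200).
#' @param window CNN window size (default 3).
#' @param seed RNG seed for initialization.
#' @param embeddings Optional [read_embeddings()] table to warm-start word
#'   vectors (must have `d` columns); POS and relation tables are always
#'   randomly initialized.
#' @return A `cdr_neural` model (untrained).
#' @export
init_neural <- function(vocabs, method = "SDP-seq+POS+HEAD", d = 200L,
                        hidden = 100L, arch = c("lstm", "cnn"),
                        n_maps = 200L, window = 3L, seed = 42L,
                        embeddings = NULL) {
  arch <- match.arg(arch)
  m <- parse_method(method)
  set.seed(seed)
  D <- if (m$use_pos) 2L * d else d
  p <- list(E_word = rand_mat(length(vocabs$word), d),
            E_rel = rand_mat(length(vocabs$rel), d))
  if (!is.null(embeddings)) {
    if (ncol(embeddings$vectors) != d) stop("embedding width != d")
    hit <- match(vocabs$word, embeddings$words)
    p$E_word[!is.na(hit), ] <- embeddings$vectors[hit[!is.na(hit)], , drop = FALSE]
  }
  if (m$use_pos) p$E_pos <- rand_mat(length(vocabs$pos), d)
  if (arch == "lstm") {
    H <- hidden
    for (g in c("i", "f", "c", "o")) {
      p[[paste0("W", g)]] <- rand_mat(H, D)
      p[[paste0("U", g)]] <- rand_mat(H, H)
      p[[paste0("b", g)]] <- numeric(H)
    }
    for (g in c("i", "f", "o")) p[[paste0("v", g)]] <- stats::runif(H, -0.1, 0.1)
    p$w_out <- stats::runif(H, -0.1, 0.1)
  } else {
    p$W_conv <- rand_mat(n_maps, window * D)
    p$b_conv <- numeric(n_maps)
    p$w_out <- stats::runif(n_maps, -0.1, 0.1)
  }
  p$b_out <- 0
  structure(list(arch = arch, method = method, base = m$base,
                 use_pos = m$use_pos, use_head = m$use_head,
                 d = d, D = D, hidden = hidden, n_maps = n_maps,
                 window = window, vocabs = vocabs, params = p),
            class = "cdr_neural")
}

#' @export
print.cdr_neural <- function(x, ...) {
  cat(sprintf("<cdr_neural %s over %s: d=%d, %s, |V_word|=%d>\n",
              toupper(x$arch), x$method, x$d,
              if (x$arch == "lstm") paste0("H=", x$hidden)
              else sprintf("%d maps, window %d", x$n_maps, x$window),
              length(x$vocabs$word)))
  invisible(x)
}

# input matrix D x T from embedding tables
input_matrix <- function(model, p, ids) {
  X <- matrix(0, model$d, length(ids$id))
  w <- ids$type == 1L
  if (any(w)) X[, w] <- t(p$E_word[ids$id[w], , drop = FALSE])
  if (any(!w)) X[, !w] <- t(p$E_rel[ids$id[!w], , drop = FALSE])
  if (model$use_pos) X <- rbind(X, t(p$E_pos[ids$pos_id, , drop = FALSE]))
  X
}

# ---- LSTM forward / backward -------------------------------------------------

#' One peephole-LSTM step
#'
#' Applies the five gate equations in order: input and forget gates peek at
#' the previous cell, the output gate peeks at the current cell.
#'
#' @param x_t Input vector (length `D`).
#' @param h_prev,c_prev Previous hidden and cell vectors (length `H`).
#' @param params List with `Wi,Wf,Wc,Wo` (`H x D`), `Ui,Uf,Uc,Uo` (`H x H`),
#'   diagonal peepholes `vi,vf,vo` and biases `bi,bf,bc,bo` (length `H`).
#' @return List with `h`, `c` and the gate activations `i`, `f`, `o`, `g`
#'   (candidate).
#' @export
lstm_step <- function(x_t, h_prev, c_prev, params) {
  p <- params
  stopifnot(length(x_t) == ncol(p$Wi), length(h_prev) == nrow(p$Wi),
            length(c_prev) == nrow(p$Wi))
  i <- sigmoid(as.vector(p$Wi %*% x_t + p$Ui %*% h_prev) + p$vi * c_prev + p$bi)
  f <- sigmoid(as.vector(p$Wf %*% x_t + p$Uf %*% h_prev) + p$vf * c_prev + p$bf)
  g <- tanh(as.vector(p$Wc %*% x_t + p$Uc %*% h_prev) + p$bc)
  c_t <- f * c_prev + i * g
  o <- sigmoid(as.vector(p$Wo %*% x_t + p$Uo %*% h_prev) + p$vo * c_t + p$bo)
  h_t <- o * tanh(c_t)
  list(h = h_t, c = c_t, i = i, f = f, o = o, g = g)
}

#' Encode a sequence with the peephole LSTM
#'
#' Recursive application of [lstm_step()] from zero initial state; the final
#' hidden state is the semantic representation of the sequence.
#'
#' @param X Input matrix `D x T` (columns are time steps).
#' @param params As in [lstm_step()].
#' @return The final hidden state `h_T` (length `H`).
#' @export
lstm_encode <- function(X, params) {
  H <- nrow(params$Wi)
  h <- numeric(H); cc <- numeric(H)
  for (t in seq_len(ncol(X))) {
    st <- lstm_step(X[, t], h, cc, params)
    h <- st$h; cc <- st$c
  }
  h
}

lstm_forward_cached <- function(X, p) {
  H <- nrow(p$Wi); T_ <- ncol(X)
  cache <- vector("list", T_)
  h <- numeric(H); cc <- numeric(H)
  for (t in seq_len(T_)) {
    st <- lstm_step(X[, t], h, cc, p)
    cache[[t]] <- c(st, list(h_prev = h, c_prev = cc))
    h <- st$h; cc <- st$c
  }
  list(h_T = h, cache = cache)
}

# dh_T: gradient wrt final hidden state; returns grads for lstm params and dX
lstm_backward <- function(X, p, fwd, dh_T) {
  H <- nrow(p$Wi); T_ <- ncol(X)
  g0 <- function(nr, nc) matrix(0, nr, nc)
  gr <- list(Wi = g0(H, nrow(X)), Wf = g0(H, nrow(X)), Wc = g0(H, nrow(X)),
             Wo = g0(H, nrow(X)), Ui = g0(H, H), Uf = g0(H, H), Uc = g0(H, H),
             Uo = g0(H, H), vi = numeric(H), vf = numeric(H), vo = numeric(H),
             bi = numeric(H), bf = numeric(H), bc = numeric(H), bo = numeric(H))
  dX <- matrix(0, nrow(X), T_)
  dh <- dh_T; dc <- numeric(H)
  for (t in rev(seq_len(T_))) {
    s <- fwd$cache[[t]]
    tc <- tanh(s$c)
    da_o <- (dh * tc) * s$o * (1 - s$o)
    dct <- dc + dh * s$o * (1 - tc^2) + da_o * p$vo
    da_i <- (dct * s$g) * s$i * (1 - s$i)
    da_f <- (dct * s$c_prev) * s$f * (1 - s$f)
    da_g <- (dct * s$i) * (1 - s$g^2)
    x_t <- X[, t]
    gr$Wi <- gr$Wi + tcrossprod(da_i, x_t); gr$Ui <- gr$Ui + tcrossprod(da_i, s$h_prev)
    gr$Wf <- gr$Wf + tcrossprod(da_f, x_t); gr$Uf <- gr$Uf + tcrossprod(da_f, s$h_prev)
    gr$Wc <- gr$Wc + tcrossprod(da_g, x_t); gr$Uc <- gr$Uc + tcrossprod(da_g, s$h_prev)
    gr$Wo <- gr$Wo + tcrossprod(da_o, x_t); gr$Uo <- gr$Uo + tcrossprod(da_o, s$h_prev)
    gr$vi <- gr$vi + da_i * s$c_prev
    gr$vf <- gr$vf + da_f * s$c_prev
    gr$vo <- gr$vo + da_o * s$c
    gr$bi <- gr$bi + da_i; gr$bf <- gr$bf + da_f
    gr$bc <- gr$bc + da_g; gr$bo <- gr$bo + da_o
    dX[, t] <- as.vector(crossprod(p$Wi, da_i) + crossprod(p$Wf, da_f) +
                           crossprod(p$Wc, da_g) + crossprod(p$Wo, da_o))
    dh <- as.vector(crossprod(p$Ui, da_i) + crossprod(p$Uf, da_f) +
                      crossprod(p$Uc, da_g) + crossprod(p$Uo, da_o))
    dc <- dct * s$f + da_i * p$vi + da_f * p$vf
  }
  list(grads = gr, dX = dX)
}

# ---- CNN forward / backward --------------------------------------------------

#' CNN sequence encoder with max-over-time pooling
#'
#' 1-D convolution (window `w`, `tanh` nonlinearity) followed by
#' componentwise max over positions; the sequence is zero-padded so that at
#' least one window exists.
#'
#' @param X Input matrix `D x T`.
#' @param W_conv Filter matrix `n_maps x (w * D)`.
#' @param b_conv Bias vector (length `n_maps`).
#' @param window Window size (default 3).
#' @return The pooled vector (length `n_maps`).
#' @export
cnn_encode <- function(X, W_conv, b_conv, window = 3L) {
  cnn_forward_cached(X, W_conv, b_conv, window)$pooled
}

cnn_forward_cached <- function(X, W_conv, b_conv, window) {
  pad <- window %/% 2L
  Xp <- cbind(matrix(0, nrow(X), pad), X, matrix(0, nrow(X), pad))
  T_ <- ncol(X)
  Xcat <- matrix(0, window * nrow(X), T_)
  for (t in seq_len(T_)) {
    Xcat[, t] <- as.vector(Xp[, t:(t + window - 1L)])
  }
  Z <- tanh(W_conv %*% Xcat + b_conv)
  amax <- apply(Z, 1L, which.max)
  pooled <- Z[cbind(seq_len(nrow(Z)), amax)]
  list(pooled = pooled, Z = Z, amax = amax, Xcat = Xcat, pad = pad)
}

cnn_backward <- function(X, W_conv, fwd, dpooled, window) {
  dZ <- matrix(0, nrow(fwd$Z), ncol(fwd$Z))
  dZ[cbind(seq_len(nrow(dZ)), fwd$amax)] <- dpooled
  dA <- dZ * (1 - fwd$Z^2)
  gr <- list(W_conv = dA %*% t(fwd$Xcat), b_conv = rowSums(dA))
  dXcat <- crossprod(W_conv, dA)
  D <- nrow(X); T_ <- ncol(X); pad <- fwd$pad
  dXp <- matrix(0, D, T_ + 2L * pad)
  for (t in seq_len(T_)) {
    dXp[, t:(t + window - 1L)] <- dXp[, t:(t + window - 1L)] +
      matrix(dXcat[, t], D, window)
  }
  list(grads = gr, dX = dXp[, (pad + 1L):(pad + T_), drop = FALSE])
}

# ---- full forward / backward over one candidate sequence ---------------------

neural_forward <- function(model, p, ids) {
  X <- input_matrix(model, p, ids)
  if (model$arch == "lstm") {
    fwd <- lstm_forward_cached(X, p)
    rep_vec <- fwd$h_T
  } else {
    fwd <- cnn_forward_cached(X, p$W_conv, p$b_conv, model$window)
    rep_vec <- fwd$pooled
  }
  z <- sum(p$w_out * rep_vec) + p$b_out
  list(prob = sigmoid(z), rep = rep_vec, fwd = fwd, X = X)
}

neural_backward <- function(model, p, ids, cache, y) {
  dz <- cache$prob - y                      # d(cross-entropy)/d(logit)
  gr <- list(w_out = dz * cache$rep, b_out = dz)
  drep <- dz * p$w_out
  if (model$arch == "lstm") {
    bk <- lstm_backward(cache$X, p, cache$fwd, drep)
  } else {
    bk <- cnn_backward(cache$X, p$W_conv, cache$fwd, drep, model$window)
  }
  gr <- c(gr, bk$grads)
  dX <- bk$dX
  gr$E_word <- matrix(0, nrow(p$E_word), model$d)
  gr$E_rel <- matrix(0, nrow(p$E_rel), model$d)
  if (model$use_pos) gr$E_pos <- matrix(0, nrow(p$E_pos), model$d)
  for (t in seq_along(ids$id)) {
    dx <- dX[seq_len(model$d), t]
    if (ids$type[[t]] == 1L) {
      gr$E_word[ids$id[[t]], ] <- gr$E_word[ids$id[[t]], ] + dx
    } else {
      gr$E_rel[ids$id[[t]], ] <- gr$E_rel[ids$id[[t]], ] + dx
    }
    if (model$use_pos) {
      gr$E_pos[ids$pos_id[[t]], ] <- gr$E_pos[ids$pos_id[[t]], ] +
        dX[(model$d + 1L):(2L * model$d), t]
    }
  }
  gr
}

neural_loss <- function(prob, y) {
  eps <- 1e-12
  -(y * log(prob + eps) + (1 - y) * log(1 - prob + eps))
}

# total loss and summed gradients over a list of id-sequences
neural_batch <- function(model, p, id_list, ys, with_grads = TRUE) {
  total <- 0
  grads <- NULL
  for (k in seq_along(id_list)) {
    cache <- neural_forward(model, p, id_list[[k]])
    total <- total + neural_loss(cache$prob, ys[[k]])
    if (with_grads) {
      g <- neural_backward(model, p, id_list[[k]], cache, ys[[k]])
      grads <- if (is.null(grads)) g else mapply(`+`, grads, g[names(grads)],
                                                 SIMPLIFY = FALSE)
    }
  }
  list(loss = total, grads = grads)
}

#' Predict candidate probabilities with a neural model
#'
#' @param object A trained `cdr_neural`.
#' @param sequences List of tibbles from [encode_input()].
#' @param ... Unused.
#' @return Numeric vector of probabilities in `(0, 1)`.
#' @export
predict.cdr_neural <- function(object, sequences, ...) {
  vapply(sequences, function(s) {
    ids <- seq_to_ids(s, object$vocabs)
    neural_forward(object, object$params, ids)$prob
  }, numeric(1))
}

#' Train a neural candidate classifier
#'
#' Minimizes cross-entropy by mini-batch gradient descent (gradients averaged
#' within each batch), with optional early stopping on a validation split.
#' Deterministic given the seed.
#'
#' @param model A `cdr_neural` from [init_neural()].
#' @param sequences List of tibbles from [encode_input()].
#' @param labels Candidate labels in `{-1, +1}` (or `{0, 1}`).
#' @param epochs,lr,batch_size Optimization hyperparameters (defaults 30,
#'   0.01, 32).
#' @param val_frac Fraction held out for early stopping (0 disables;
#'   default 0.1).
#' @param patience Epochs without validation improvement before stopping
#'   (default 5).
#' @param seed RNG seed controlling shuffling and the validation split.
#' @return The model with trained parameters and a `$log` tibble
#'   (epoch, mean training loss, validation loss).
#' @export
train_neural <- function(model, sequences, labels, epochs = 30L, lr = 0.01,
                         batch_size = 32L, val_frac = 0.1, patience = 5L,
                         seed = 42L) {
  if (length(sequences) == 0L) stop("empty training set")
  ys <- as.numeric(labels > 0)
  id_list <- lapply(sequences, seq_to_ids, vocabs = model$vocabs)
  set.seed(seed)
  n <- length(id_list)
  n_val <- if (val_frac > 0) max(1L, floor(val_frac * n)) else 0L
  val_idx <- if (n_val > 0L && n - n_val >= 2L) sample.int(n, n_val) else integer()
  tr_idx <- setdiff(seq_len(n), val_idx)
  p <- model$params
  best <- list(loss = Inf, p = p, since = 0L)
  log <- list()
  for (epoch in seq_len(epochs)) {
    ord <- sample(tr_idx)
    ep_loss <- 0
    for (start in seq(1L, length(ord), by = batch_size)) {
      bi <- ord[start:min(start + batch_size - 1L, length(ord))]
      bt <- neural_batch(model, p, id_list[bi], ys[bi])
      ep_loss <- ep_loss + bt$loss
      step <- lr / length(bi)
      p <- mapply(function(par, g) par - step * g, p, bt$grads[names(p)],
                  SIMPLIFY = FALSE)
    }
    val_loss <- if (length(val_idx)) {
      neural_batch(model, p, id_list[val_idx], ys[val_idx],
                   with_grads = FALSE)$loss / length(val_idx)
    } else NA_real_
    log[[epoch]] <- tibble(epoch = epoch, train_loss = ep_loss / length(tr_idx),
                           val_loss = val_loss)
    if (length(val_idx)) {
      if (val_loss < best$loss - 1e-6) {
        best <- list(loss = val_loss, p = p, since = 0L)
      } else {
        best$since <- best$since + 1L
        if (best$since >= patience) break
      }
    }
  }
  model$params <- if (length(val_idx)) best$p else p
  model$log <- bind_rows(log)
  model
}

# ---- parameter flattening (gradient checks, checkpoints) --------------------

flatten_params <- function(p) unlist(p, use.names = FALSE)

unflatten_params <- function(p, flat) {
  out <- p; k <- 0L
  for (nm in names(p)) {
    len <- length(p[[nm]])
    v <- flat[(k + 1L):(k + len)]
    out[[nm]] <- if (is.matrix(p[[nm]])) matrix(v, nrow(p[[nm]]), ncol(p[[nm]])) else v
    k <- k + len
  }
  out
}

#' Compare analytic and numeric gradients of a neural model
#'
#' Central finite differences of the total loss on the given sequences,
#' against the BPTT/backprop gradients, for every parameter tensor
#' (embeddings included).
#'
#' @param model A `cdr_neural`.
#' @param sequences List of tibbles from [encode_input()].
#' @param labels Labels in `{-1, +1}` or `{0, 1}`.
#' @param eps Finite-difference step (default 1e-5).
#' @param floor Denominator floor guarding the relative-error quotient
#'   against catastrophic cancellation on near-zero entries (default 1e-3:
#'   entries with `|ga| + |gn|` below it are compared at absolute precision
#'   `floor * tolerance`).
#' @return Tibble with per-tensor maximum relative error
#'   (`|ga - gn| / max(floor, |ga| + |gn|)`).
#' @export
gradient_check <- function(model, sequences, labels, eps = 1e-5, floor = 1e-3) {
  ys <- as.numeric(labels > 0)
  id_list <- lapply(sequences, seq_to_ids, vocabs = model$vocabs)
  p <- model$params
  analytic <- neural_batch(model, p, id_list, ys)$grads[names(p)]
  loss_at <- function(flat) {
    neural_batch(model, unflatten_params(p, flat), id_list, ys,
                 with_grads = FALSE)$loss
  }
  flat <- flatten_params(p)
  rows <- list()
  k <- 0L
  for (nm in names(p)) {
    len <- length(p[[nm]])
    ga <- as.vector(analytic[[nm]])
    gn <- numeric(len)
    for (u in seq_len(len)) {
      fp <- flat; fp[k + u] <- fp[k + u] + eps
      fm <- flat; fm[k + u] <- fm[k + u] - eps
      gn[u] <- (loss_at(fp) - loss_at(fm)) / (2 * eps)
    }
    rel <- abs(ga - gn) / pmax(floor, abs(ga) + abs(gn))
    rows[[nm]] <- tibble(tensor = nm, max_rel_err = max(rel),
                         max_abs_grad = max(abs(ga)))
    k <- k + len
  }
  bind_rows(rows)
}
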