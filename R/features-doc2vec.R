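# Paragraph-vector (doc2vec) document embeddings.
#
# A compact trainer for the two classic paragraph-vector objectives with
# negative sampling:
#   DM   (distributed memory)       - predict each word from the mean of the
#                                     document vector and the W-window context
#                                     word vectors
#   DBOW (distributed bag of words) - predict each word from the document
#                                     vector alone
# Written for moderate corpora (the unit of analysis here is hundreds of
# notes); it is deliberately single-threaded so a fixed seed reproduces the
# embedding matrix bit for bit.

#' Paragraph-vector configuration
#'
#' @param D Embedding dimension (positive integer).
#' @param W Window size: number of context words on each side (DM only).
#' @param mode `"DM"` or `"DBOW"`.
#' @return A `doc2vec_config`.
#' @export
doc2vec_config <- function(D = 100, W = 5, mode = c("DM", "DBOW")) {
  if (!is_count(D)) stop_bad("D must be a positive integer")
  if (!is_count(W)) stop_bad("W must be a positive integer")
  mode <- match.arg(mode)
  structure(list(D = as.integer(D), W = as.integer(W), mode = mode),
    class = "doc2vec_config"
  )
}

#' Train paragraph vectors for a corpus
#'
#' @param corpus A [coded_corpus()] with at least 10 notes.
#' @param config A [doc2vec_config()].
#' @param seed Integer seed; fixes initialization and sampling, so reruns
#'   give identical matrices.
#' @param epochs Training epochs.
#' @param negative Negative samples per target word.
#' @param alpha,min_alpha Initial and final learning rate (linear decay).
#' @return A [feature_matrix()] with one `D`-dimensional row per note.
#' @export
doc2vec_features <- function(corpus, config = doc2vec_config(), seed = 1L,
                             epochs = 15, negative = 5, alpha = 0.05,
                             min_alpha = 0.001) {
  stopifnot(inherits(corpus, "coded_corpus"), inherits(config, "doc2vec_config"))
  if (length(corpus$note_id) < 10) stop_bad("doc2vec needs at least 10 notes")
  docs <- corpus$tokens
  vocab <- sort(unique(unlist(docs)))
  if (length(vocab) < 2) stop_bad("corpus vocabulary too small")
  vmap <- stats::setNames(seq_along(vocab), vocab)
  docs_idx <- lapply(docs, function(t) unname(vmap[t]))
  V <- length(vocab)
  D <- config$D
  n_doc <- length(docs_idx)

  # unigram^0.75 negative-sampling table
  freq <- tabulate(unlist(docs_idx), nbins = V)
  neg_prob <- freq^0.75
  neg_prob <- neg_prob / sum(neg_prob)

  with_seed(derive_seed(seed, 555001), {
    docvec <- matrix(stats::runif(n_doc * D, -0.5, 0.5) / D, n_doc, D)
    wordvec_in <- matrix(stats::runif(V * D, -0.5, 0.5) / D, V, D)
    wordvec_out <- matrix(0, V, D)

    total_steps <- epochs * n_doc
    step <- 0
    for (ep in seq_len(epochs)) {
      for (d in seq_len(n_doc)) {
        step <- step + 1
        lr <- alpha + (min_alpha - alpha) * (step - 1) / max(1, total_steps - 1)
        widx <- docs_idx[[d]]
        L <- length(widx)
        if (L == 0) next
        negs <- sample.int(V, L * negative, replace = TRUE, prob = neg_prob)
        for (p in seq_len(L)) {
          target <- widx[p]
          if (config$mode == "DM") {
            lo <- max(1, p - config$W); hi <- min(L, p + config$W)
            ctx <- widx[setdiff(lo:hi, p)]
            h <- if (length(ctx)) {
              (docvec[d, ] + colSums(wordvec_in[ctx, , drop = FALSE])) /
                (1 + length(ctx))
            } else {
              docvec[d, ]
            }
          } else {
            ctx <- integer(0)
            h <- docvec[d, ]
          }
          outs <- c(target, negs[((p - 1) * negative + 1):(p * negative)])
          lab <- c(1, numeric(negative))
          u <- wordvec_out[outs, , drop = FALSE]
          g <- (1 / (1 + exp(-as.numeric(u %*% h))) - lab) * lr # dL/dscore
          h_grad <- as.numeric(crossprod(u, g))
          wordvec_out[outs, ] <- u - outer(g, h)
          if (config$mode == "DM") {
            scale <- 1 / (1 + length(ctx))
            docvec[d, ] <- docvec[d, ] - h_grad * scale
            if (length(ctx)) {
              wordvec_in[ctx, ] <- wordvec_in[ctx, , drop = FALSE] -
                matrix(h_grad * scale, length(ctx), D, byrow = TRUE)
            }
          } else {
            docvec[d, ] <- docvec[d, ] - h_grad
          }
        }
      }
    }
    feature_matrix(
      docvec, corpus$note_id, sprintf("pv%03d", seq_len(D)),
      provenance = list(
        family = "doc2vec", D = D, W = config$W, mode = config$mode
      )
    )
  })
}
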