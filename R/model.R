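## Two-layered SVM over MDD-identified substrate motifs.
##
## First layer: one RBF-kernel SVM per motif subgroup, trained on the
## subgroup's positives plus negatives sampled at ~1:8 from the negative
## pool, on scaled hybrid features (default AAC + PSSM). Second layer: an
## RBF-kernel SVM over the vector of first-layer probability estimates.
## The meta-features used to TRAIN the second layer are produced by
## k-fold cross-fitting of the first layer, so no fragment is scored by a
## model that saw it; at prediction time the full first-layer models are
## used.

#' Sample negatives for a motif subgroup
#'
#' Uniform sample without replacement of `round(ratio * n_pos)` negative
#' fragments; if the pool is smaller, the whole pool is returned with a
#' warning. Deterministic given the seed.
#'
#' @param n_pos Number of positives in the subgroup.
#' @param pool A `palm_fragments` dataset (or data.frame) of negatives.
#' @param ratio Negatives per positive (default 8, approximating the
#'   710:5676 class ratio).
#' @param seed Integer seed.
#' @return Integer row indices into `pool`.
#' @export
sample_negatives <- function(n_pos, pool, ratio = 8, seed = 1L) {
  n_avail <- if (is.data.frame(pool)) nrow(pool) else length(pool)
  if (n_avail == 0L) stop("negative pool is empty")
  want <- round(ratio * n_pos)
  if (want > n_avail) {
    warning("negative pool has only ", n_avail, " fragments; requested ",
            want, " - using the whole pool")
    return(seq_len(n_avail))
  }
  with_seed(seed, sample.int(n_avail, want))
}

#' Build the fitted feature context for a training set
#'
#' The position weight matrix and (unless an external profile is supplied)
#' the internal PSSM profile are fitted on the positive training
#' fragments only, mirroring how the published profiles are derived from
#' the modified-site sequences.
#'
#' @param positives Positive training fragments.
#' @param recipe Feature scheme names (see [encode_features()]).
#' @param asa_table Optional ASA table for the `"asa"` scheme.
#' @param pssm Optional external `"pssm_profile"` overriding the internal
#'   one.
#' @return Context list for [encode_features()].
#' @export
build_feature_context <- function(positives, recipe = c("aac", "pssm"),
                                  asa_table = NULL, pssm = NULL) {
  ctx <- list()
  if ("pwm" %in% recipe) ctx$pwm <- build_pwm(positives)
  if ("pssm" %in% recipe) ctx$pssm <- pssm %||% build_internal_pssm(positives)
  if ("asa" %in% recipe) {
    if (is.null(asa_table)) stop("recipe 'asa' needs an asa_table")
    ctx$asa_table <- asa_table
  }
  ctx
}

#' Train one motif-subgroup SVM
#'
#' Fits the min-max scaler on this model's own training features, then an
#' RBF-kernel SVM with probability outputs.
#'
#' @param pos_features,neg_features Raw (unscaled) feature matrices of the
#'   subgroup positives and sampled negatives.
#' @param params An [svm_params()].
#' @param id Subgroup identifier (leaf id).
#' @return List of class `"subgroup_model"`.
#' @export
train_subgroup_model <- function(pos_features, neg_features,
                                 params = svm_params(), id = "Palm1") {
  if (nrow(pos_features) == 0L || nrow(neg_features) == 0L) {
    stop("subgroup training needs both classes")
  }
  x <- rbind(pos_features, neg_features)
  y <- rep(c(TRUE, FALSE), c(nrow(pos_features), nrow(neg_features)))
  scaler <- fit_scaler(x)
  svm <- svm_train(apply_scaler(scaler, x), y, params = params,
                   probability = TRUE)
  structure(list(id = id, scaler = scaler, svm = svm, params = params,
                 n_pos = nrow(pos_features), n_neg = nrow(neg_features)),
            class = "subgroup_model")
}

subgroup_probability <- function(model, features) {
  svm_probability(model$svm, apply_scaler(model$scaler, features))
}

#' First-layer probability matrix
#'
#' @param features Raw feature matrix (one row per fragment, encoded under
#'   the models' shared recipe).
#' @param models List of `"subgroup_model"` objects.
#' @return Matrix `|fragments| x |models|` of probabilities in \[0, 1\],
#'   columns named by subgroup id, row order preserved.
#' @export
first_layer_probabilities <- function(features, models) {
  if (!length(models)) stop("no subgroup models given")
  out <- vapply(models, subgroup_probability, numeric(nrow(features)),
                features = features)
  out <- matrix(out, nrow = nrow(features))
  colnames(out) <- vapply(models, `[[`, character(1), "id")
  out
}

#' Train the two-layered motif model
#'
#' Learns (or reuses) the MDD motif tree on the positive fragments, trains
#' one first-layer SVM per motif subgroup (negatives sampled at
#' `1:ratio`), produces cross-fitted first-layer probabilities for every
#' training fragment, and trains the second-layer SVM on those
#' meta-features for all positives and all negatives.
#'
#' @param dataset A labelled `"palm_fragments"` dataset.
#' @param tree Optional pre-built `"mdd_tree"` over the dataset's
#'   positives (in positive-subset row order); built when `NULL`.
#' @param recipe Feature recipe (default the AAC + PSSM hybrid).
#' @param scheme An [aa_group_scheme()].
#' @param mdd_cfg An [mdd_config()].
#' @param params,meta_params [svm_params()] for the two layers.
#' @param ratio Negatives per positive in each subgroup (default 8).
#' @param crossfit_folds Folds used to cross-fit first-layer scores for
#'   the meta-training features (default 5).
#' @param seed Integer seed driving negative sampling and fold assignment.
#' @param asa_table,pssm Passed to [build_feature_context()].
#' @param threshold Decision threshold on the second-layer probability.
#' @return Object of class `"two_layer_model"`.
#' @export
train_two_layer <- function(dataset, tree = NULL, recipe = c("aac", "pssm"),
                            scheme = aa_group_scheme(),
                            mdd_cfg = mdd_config(), params = svm_params(),
                            meta_params = svm_params(), ratio = 8,
                            crossfit_folds = 5L, seed = 1L,
                            asa_table = NULL, pssm = NULL, threshold = 0.5) {
  stopifnot(inherits(dataset, "palm_fragments"))
  pos_idx <- which(dataset$label == "positive")
  neg_idx <- which(dataset$label == "negative")
  if (!length(pos_idx) || !length(neg_idx)) {
    stop("dataset must contain both classes")
  }
  positives <- dataset[pos_idx, , drop = FALSE]
  attr(positives, "n") <- attr(dataset, "n")
  class(positives) <- class(dataset)

  if (is.null(tree)) tree <- mdd_cluster(positives, scheme, mdd_cfg)
  leaves <- mdd_leaves(tree)

  ctx <- build_feature_context(positives, recipe, asa_table = asa_table,
                               pssm = pssm)
  features <- encode_features(dataset, recipe, ctx)

  n_all <- nrow(dataset)
  meta <- matrix(NA_real_, nrow = n_all, ncol = length(leaves),
                 dimnames = list(NULL, names(leaves)))
  models <- vector("list", length(leaves))
  names(models) <- names(leaves)

  for (k in seq_along(leaves)) {
    id <- names(leaves)[k]
    pos_rows <- pos_idx[leaves[[k]]]
    if (!length(pos_rows)) stop("motif subgroup ", id, " has zero positives")
    neg_rows <- neg_idx[sample_negatives(length(pos_rows), dataset[neg_idx, ],
                                         ratio = ratio,
                                         seed = derive_seed(seed, k))]
    train_rows <- c(pos_rows, neg_rows)
    models[[k]] <- train_subgroup_model(features[pos_rows, , drop = FALSE],
                                        features[neg_rows, , drop = FALSE],
                                        params = params, id = id)
    ## out-of-training fragments: scored by the full subgroup model
    other <- setdiff(seq_len(n_all), train_rows)
    if (length(other)) {
      meta[other, k] <- subgroup_probability(models[[k]],
                                             features[other, , drop = FALSE])
    }
    ## training fragments: cross-fitted scores
    meta[train_rows, k] <-
      crossfit_scores(features, train_rows,
                      dataset$label[train_rows] == "positive",
                      models[[k]], params,
                      folds = crossfit_folds,
                      seed = derive_seed(seed, 1000L + k))
  }

  y_all <- dataset$label == "positive"
  meta_scaler <- fit_scaler(meta)
  meta_svm <- svm_train(apply_scaler(meta_scaler, meta), y_all,
                        params = meta_params, probability = TRUE)

  structure(list(tree = tree, recipe = recipe, context = ctx,
                 subgroup_models = models, meta_scaler = meta_scaler,
                 meta_svm = meta_svm, params = params,
                 meta_params = meta_params, ratio = ratio,
                 threshold = threshold, seed = seed,
                 n = attr(dataset, "n"),
                 n_pos = length(pos_idx), n_neg = length(neg_idx)),
            class = "two_layer_model")
}

## Cross-fitted first-layer probabilities for the rows a subgroup model was
## trained on. Falls back to in-sample scores (with a warning) when the
## class counts cannot sustain >= 2 stratified folds.
crossfit_scores <- function(features, train_rows, y_train, full_model,
                            params, folds, seed) {
  n1 <- sum(y_train); n0 <- sum(!y_train)
  folds <- min(folds, n1, n0)
  if (folds < 2L) {
    warning("subgroup ", full_model$id,
            " too small to cross-fit; using in-sample first-layer scores")
    return(subgroup_probability(full_model,
                                features[train_rows, , drop = FALSE]))
  }
  assign <- stratified_folds(y_train, folds, seed)
  out <- numeric(length(train_rows))
  for (f in seq_len(folds)) {
    tr <- train_rows[assign != f]
    te <- train_rows[assign == f]
    ytr <- y_train[assign != f]
    sub <- train_subgroup_model(features[tr[ytr], , drop = FALSE],
                                features[tr[!ytr], , drop = FALSE],
                                params = params, id = full_model$id)
    out[assign == f] <- subgroup_probability(sub,
                                             features[te, , drop = FALSE])
  }
  out
}

## Seeded stratified fold assignment (fold sizes differ by <= 1 per class).
stratified_folds <- function(y, k, seed) {
  assign <- integer(length(y))
  with_seed(seed, {
    for (cls in unique(y)) {
      idx <- which(y == cls)
      assign[idx] <- sample(rep(seq_len(k), length.out = length(idx)))
    }
  })
  assign
}

#' Second-layer probabilities for fragments
#'
#' Encodes the fragments under the model's recipe and fitted context,
#' scores them with the full first-layer models, and returns the
#' second-layer probability of S-palmitoylation.
#'
#' @param model A `"two_layer_model"`.
#' @param fragments A `palm_fragments` dataset or character vector.
#' @return Numeric probabilities in \[0, 1\].
#' @export
predict_two_layer <- function(model, fragments) {
  features <- encode_features(fragments, model$recipe, model$context)
  fl <- first_layer_probabilities(features, model$subgroup_models)
  svm_probability(model$meta_svm, apply_scaler(model$meta_scaler, fl))
}

#' Predict S-palmitoylation sites on proteins
#'
#' Scores every cysteine of every input protein: window extraction,
#' first-layer motif probabilities, second-layer probability, binary call
#' at the threshold, and the routed motif subgroup.
#'
#' @param proteins Named character vector of sequences (see
#'   [read_fasta()]).
#' @param model A `"two_layer_model"`.
#' @param threshold Decision threshold (default the model's).
#' @return data.frame with columns `protein_id`, `position`, `residue`,
#'   `probability`, `call`, `motif_subgroup`, `fragment`.
#' @export
predict_sites <- function(proteins, model, threshold = NULL) {
  if (!length(proteins)) stop("no protein sequences given")
  threshold <- threshold %||% model$threshold
  rows <- lapply(names(proteins) %||% as.character(seq_along(proteins)),
                 function(pid) {
    seq <- clean_sequences(proteins[[pid]])
    cys <- which(strsplit(seq, "", fixed = TRUE)[[1]] == "C")
    if (!length(cys)) return(NULL)
    data.frame(protein_id = pid, position = cys,
               fragment = extract_fragment(seq, cys, model$n),
               stringsAsFactors = FALSE)
  })
  cand <- do.call(rbind, rows)
  empty <- data.frame(protein_id = character(), position = integer(),
                      residue = character(), probability = numeric(),
                      call = logical(), motif_subgroup = character(),
                      fragment = character(), stringsAsFactors = FALSE)
  if (is.null(cand)) return(empty)
  prob <- predict_two_layer(model, cand$fragment)
  motif <- assign_subgroup(cand$fragment, model$tree)
  ## a routed leaf without a trainable model falls back to the strongest
  ## first-layer probability
  missing_model <- !motif %in% names(model$subgroup_models)
  if (any(missing_model)) {
    features <- encode_features(cand$fragment[missing_model], model$recipe,
                                model$context)
    fl <- first_layer_probabilities(features, model$subgroup_models)
    motif[missing_model] <- colnames(fl)[max.col(fl, ties.method = "first")]
  }
  data.frame(protein_id = cand$protein_id, position = cand$position,
             residue = substring(cand$fragment, model$n + 1L, model$n + 1L),
             probability = prob, call = prob >= threshold,
             motif_subgroup = motif, fragment = cand$fragment,
             stringsAsFactors = FALSE)
}

#' Grid search for SVM hyperparameters
#'
#' Evaluates each (gamma, cost) grid point by stratified k-fold
#' cross-validated MCC of a single SVM on the encoded dataset and returns
#' the best point (ties: smaller cost, then smaller gamma).
#'
#' @param dataset A labelled `"palm_fragments"` dataset.
#' @param gammas,costs Numeric grids (defaults `2^(-7..1)` and
#'   `2^(-3..7)`).
#' @param recipe Feature recipe.
#' @param folds Number of folds (default 3).
#' @param seed Integer seed.
#' @return The winning [svm_params()], with the grid results attached as
#'   attribute `"results"`.
#' @export
grid_search <- function(dataset, gammas = 2^seq(-7, 1), costs = 2^seq(-3, 7),
                        recipe = c("aac", "pssm"), folds = 3L, seed = 1L) {
  stopifnot(length(gammas) > 0, length(costs) > 0)
  y <- dataset$label == "positive"
  assign <- stratified_folds(y, folds, seed)
  grid <- expand.grid(cost = sort(costs), gamma = sort(gammas),
                      KEEP.OUT.ATTRS = FALSE)
  grid$mcc <- NA_real_
  ## per-fold feature contexts fitted on the training part only
  fold_data <- lapply(seq_len(folds), function(f) {
    tr <- which(assign != f)
    pos_tr <- dataset[intersect(tr, which(y)), , drop = FALSE]
    attr(pos_tr, "n") <- attr(dataset, "n"); class(pos_tr) <- class(dataset)
    ctx <- build_feature_context(pos_tr, recipe)
    feat <- encode_features(dataset, recipe, ctx)
    scaler <- fit_scaler(feat[tr, , drop = FALSE])
    list(tr = tr, te = which(assign == f), x = apply_scaler(scaler, feat))
  })
  for (g in seq_len(nrow(grid))) {
    p <- svm_params(gamma = grid$gamma[g], cost = grid$cost[g])
    mccs <- vapply(fold_data, function(fd) {
      m <- svm_train(fd$x[fd$tr, , drop = FALSE], y[fd$tr], params = p,
                     probability = FALSE)
      calls <- svm_decision(m, fd$x[fd$te, , drop = FALSE]) > 0
      classification_metrics(confusion(y[fd$te], calls))$MCC
    }, numeric(1))
    grid$mcc[g] <- mean(mccs)
  }
  best <- grid[order(-grid$mcc, grid$cost, grid$gamma), ][1L, ]
  out <- svm_params(gamma = best$gamma, cost = best$cost)
  attr(out, "results") <- grid
  out
}
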