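## Text-only model persistence: a model archive is a directory holding a
## JSON manifest, the motif tree, the fitted feature context, and one
## sub-directory per SVM (support vectors as TSV, coefficients in JSON).

ARCHIVE_VERSION <- "1"

svm_to_dir <- function(svm, dir) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  jsonlite::write_json(list(b = svm$b, gamma = svm$gamma, cost = svm$cost,
                            n_features = svm$n_features,
                            platt = svm$platt, coef = svm$coef),
                       file.path(dir, "svm.json"),
                       auto_unbox = TRUE, digits = NA)
  utils::write.table(format(svm$sv_x, digits = 17, scientific = TRUE,
                            trim = TRUE),
                     file.path(dir, "support_vectors.tsv"), sep = "\t",
                     quote = FALSE, row.names = FALSE, col.names = FALSE)
  invisible(dir)
}

svm_from_dir <- function(dir) {
  meta <- jsonlite::read_json(file.path(dir, "svm.json"), simplifyVector = TRUE)
  sv <- as.matrix(utils::read.table(file.path(dir, "support_vectors.tsv"),
                                    sep = "\t", header = FALSE))
  dimnames(sv) <- NULL
  structure(list(sv_x = sv, coef = meta$coef, b = meta$b, gamma = meta$gamma,
                 cost = meta$cost, n_features = meta$n_features,
                 platt = if (!is.null(meta$platt)) as.list(meta$platt),
                 iterations = NA_integer_, converged = TRUE),
            class = "palm_svm")
}

## jsonlite writes NULL list elements as {}; restore them to NULL so that
## svm_params(gamma = NULL) survives a manifest round-trip.
params_from_json <- function(x) {
  x <- as.list(x)
  keep <- vapply(x, function(v) is.numeric(v) && length(v) == 1L, logical(1))
  do.call(svm_params, x[keep])
}

scaler_to_df <- function(scaler) {
  data.frame(min = scaler$min, max = scaler$max)
}

scaler_from_df <- function(df) {
  structure(list(min = df$min, max = df$max), class = "palm_scaler")
}

#' Save / load a two-layered model archive
#'
#' The archive is a directory of plain-text files: `manifest.json`
#' (recipe, parameters, sizes, seed, version), `tree.json`, the fitted
#' PWM / PSSM context, per-subgroup scaler + SVM, and the stacking SVM.
#'
#' @param model A `"two_layer_model"`.
#' @param dir Archive directory (created if missing).
#' @export
save_model <- function(model, dir) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  manifest <- list(package = "mddpalm", archive_version = ARCHIVE_VERSION,
                   recipe = model$recipe, n = model$n,
                   threshold = model$threshold, ratio = model$ratio,
                   seed = model$seed, n_pos = model$n_pos,
                   n_neg = model$n_neg,
                   params = unclass(model$params),
                   meta_params = unclass(model$meta_params),
                   subgroups = names(model$subgroup_models))
  jsonlite::write_json(manifest, file.path(dir, "manifest.json"),
                       auto_unbox = TRUE, digits = NA, pretty = TRUE)
  write_mdd_tree(model$tree, file.path(dir, "tree.json"))
  if (!is.null(model$context$pwm)) {
    write_pwm(model$context$pwm, file.path(dir, "pwm.tsv"))
  }
  if (!is.null(model$context$pssm)) {
    ## full-precision profile (the PSI-BLAST ASCII exporter rounds to 2 dp)
    prof <- model$context$pssm
    df <- data.frame(offset = rownames(prof),
                     format(unclass(prof), digits = 17, trim = TRUE),
                     check.names = FALSE)
    write_tsv(df, file.path(dir, "pssm_profile.tsv"))
  }
  if (!is.null(model$context$asa_table)) {
    write_tsv(model$context$asa_table, file.path(dir, "asa.tsv"))
  }
  for (id in names(model$subgroup_models)) {
    sm <- model$subgroup_models[[id]]
    sdir <- file.path(dir, paste0("subgroup_", id))
    svm_to_dir(sm$svm, sdir)
    write_tsv(scaler_to_df(sm$scaler), file.path(sdir, "scaler.tsv"))
    jsonlite::write_json(list(id = sm$id, n_pos = sm$n_pos, n_neg = sm$n_neg,
                              params = unclass(sm$params)),
                         file.path(sdir, "meta.json"),
                         auto_unbox = TRUE, digits = NA)
  }
  svm_to_dir(model$meta_svm, file.path(dir, "meta"))
  write_tsv(scaler_to_df(model$meta_scaler), file.path(dir, "meta", "scaler.tsv"))
  invisible(dir)
}

#' @rdname save_model
#' @export
load_model <- function(dir) {
  mpath <- file.path(dir, "manifest.json")
  if (!file.exists(mpath)) stop("not a model archive (no manifest.json): ", dir)
  manifest <- jsonlite::read_json(mpath, simplifyVector = TRUE)
  if (!identical(as.character(manifest$archive_version), ARCHIVE_VERSION)) {
    stop("model archive version ", manifest$archive_version,
         " is not supported (expected ", ARCHIVE_VERSION, ")")
  }
  tree <- read_mdd_tree(file.path(dir, "tree.json"))
  ctx <- list()
  if (file.exists(file.path(dir, "pwm.tsv"))) {
    df <- read_tsv(file.path(dir, "pwm.tsv"))
    pwm <- as.matrix(df[, -1, drop = FALSE])
    dimnames(pwm) <- list(df$symbol, colnames(df)[-1])
    class(pwm) <- c("palm_pwm", class(pwm))
    ctx$pwm <- pwm
  }
  if (file.exists(file.path(dir, "pssm_profile.tsv"))) {
    df <- read_tsv(file.path(dir, "pssm_profile.tsv"))
    scores <- as.matrix(df[, -1, drop = FALSE])
    mode(scores) <- "double"
    ctx$pssm <- new_pssm_profile(scores, (nrow(scores) - 1L) %/% 2L)
  }
  if (file.exists(file.path(dir, "asa.tsv"))) {
    ctx$asa_table <- read_tsv(file.path(dir, "asa.tsv"))
  }
  models <- lapply(manifest$subgroups, function(id) {
    sdir <- file.path(dir, paste0("subgroup_", id))
    meta <- jsonlite::read_json(file.path(sdir, "meta.json"),
                                simplifyVector = TRUE)
    structure(list(id = meta$id,
                   scaler = scaler_from_df(read_tsv(file.path(sdir, "scaler.tsv"))),
                   svm = svm_from_dir(sdir),
                   params = params_from_json(meta$params),
                   n_pos = meta$n_pos, n_neg = meta$n_neg),
              class = "subgroup_model")
  })
  names(models) <- manifest$subgroups
  structure(list(tree = tree, recipe = manifest$recipe, context = ctx,
                 subgroup_models = models,
                 meta_scaler = scaler_from_df(read_tsv(file.path(dir, "meta", "scaler.tsv"))),
                 meta_svm = svm_from_dir(file.path(dir, "meta")),
                 params = params_from_json(manifest$params),
                 meta_params = params_from_json(manifest$meta_params),
                 ratio = manifest$ratio, threshold = manifest$threshold,
                 seed = manifest$seed, n = manifest$n,
                 n_pos = manifest$n_pos, n_neg = manifest$n_neg),
            class = "two_layer_model")
}
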