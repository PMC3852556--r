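# Plain-text (JSON) model/ensemble serialization with a versioned schema.
# Numbers are written with 17 significant digits, which round-trips IEEE
# doubles exactly.

SCHEMA_VERSION <- "iaspls-model-1"

model_to_list <- function(model) {
  list(schema = SCHEMA_VERSION,
       weight_vectors = model$weight_vectors,
       loadings = model$loadings,
       y_loadings = model$y_loadings,
       coefficients = model$coefficients,
       intercept = model$intercept,
       omega_final = model$omega_final,
       n_components = model$n_components,
       hyperparams = model$hyperparams,
       iterations_run = model$iterations_run,
       converged = model$converged,
       standardization = model$standardization)
}

list_to_model <- function(x) {
  if (!identical(x$schema, SCHEMA_VERSION)) {
    stop("unsupported model schema: ", x$schema %||% "<missing>",
         call. = FALSE)
  }
  ncomp <- as.integer(x$n_components)
  st <- x$standardization
  p <- as.integer(st$p)
  as_mat <- function(m) {
    m <- if (is.list(m)) do.call(rbind, lapply(m, as.numeric)) else as.matrix(m)
    matrix(as.numeric(m), nrow = p, ncol = ncomp)
  }
  structure(list(weight_vectors = as_mat(x$weight_vectors),
                 loadings = as_mat(x$loadings),
                 y_loadings = as.numeric(x$y_loadings),
                 coefficients = as.numeric(x$coefficients),
                 intercept = as.numeric(x$intercept),
                 omega_final = as.numeric(x$omega_final),
                 n_components = ncomp,
                 hyperparams = x$hyperparams,
                 iterations_run = as.integer(x$iterations_run),
                 converged = as.logical(x$converged),
                 standardization = list(
                   column_means = as.numeric(st$column_means),
                   column_sds = as.numeric(st$column_sds),
                   dropped = as.integer(unlist(st$dropped)),
                   p = p)),
            class = "iaspls_model")
}

#' Serialize a fitted model or ensemble to JSON
#'
#' Plain-text, versioned schema; numeric round-trip is exact.
#'
#' @param model an `iaspls_model`.
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_iaspls_model <- function(model, path) {
  stopifnot(inherits(model, "iaspls_model"))
  jsonlite::write_json(model_to_list(model), path, digits = I(17),
                       auto_unbox = TRUE, null = "null", pretty = TRUE)
  invisible(path)
}

#' @rdname write_iaspls_model
#' @export
read_iaspls_model <- function(path) {
  if (!file.exists(path)) stop("file not found: ", path, call. = FALSE)
  list_to_model(jsonlite::read_json(path, simplifyVector = TRUE))
}

#' @rdname write_iaspls_model
#' @param ensemble a `voting_ensemble` whose members are `iaspls_model`s.
#' @export
write_voting_ensemble <- function(ensemble, path) {
  stopifnot(inherits(ensemble, "voting_ensemble"))
  x <- list(schema = "iaspls-ensemble-1",
            K = ensemble$K, seed = ensemble$seed,
            hyperparams = ensemble$hyperparams,
            members = lapply(ensemble$members, model_to_list))
  jsonlite::write_json(x, path, digits = I(17), auto_unbox = TRUE,
                       null = "null", pretty = TRUE)
  invisible(path)
}

#' @rdname write_iaspls_model
#' @export
read_voting_ensemble <- function(path) {
  if (!file.exists(path)) stop("file not found: ", path, call. = FALSE)
  x <- jsonlite::read_json(path, simplifyVector = FALSE)
  if (!identical(x$schema, "iaspls-ensemble-1")) {
    stop("unsupported ensemble schema: ", x$schema %||% "<missing>",
         call. = FALSE)
  }
  members <- lapply(x$members, function(m) {
    list_to_model(jsonlite::parse_json(jsonlite::toJSON(m, digits = I(17),
                                                        auto_unbox = TRUE),
                                       simplifyVector = TRUE))
  })
  structure(list(K = as.integer(x$K), members = members,
                 seed = as.integer(x$seed),
                 predict_member = function(model, X) predict(model, X)$labels,
                 hyperparams = x$hyperparams),
            class = "voting_ensemble")
}
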