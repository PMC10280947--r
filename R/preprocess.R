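#' Encode a cohort as a numeric matrix
#'
#' Builds the fixed-layout numeric representation shared by the GAN:
#' numeric variables (`age`, `n_televisits`) are standardized with the
#' population mean/SD (divide-by-n), categorical variables (`gender`,
#' `site`, `metastatic`, `bone_mets`, `btcp`, `neuropathic`, `ecog`,
#' `med_gt60`) become full one-hot indicator blocks (no reference level is
#' dropped, so decoding can arg-max over every level). Column order is
#' fixed: `age`, then the categorical blocks in the order above, then
#' `n_televisits` — 31 columns in total.
#'
#' A zero-variance numeric column falls back to SD 1 with a warning. When a
#' fitted `map` is supplied its parameters are reused; an unseen category
#' is an error naming the variable and value.
#'
#' @param cohort a non-empty `patient_cohort` (the `patient_id` and
#'   `outcome` columns are not encoded).
#' @param map optionally, an `encoding_map` fitted on another cohort.
#' @return a list with `x` (the numeric matrix) and `map` (the
#'   `encoding_map` used).
#' @export
encode_cohort <- function(cohort, map = NULL) {
  if (nrow(cohort) == 0) stop("cannot encode an empty cohort")
  if (is.null(map)) map <- fit_encoding_map(cohort)
  stopifnot(inherits(map, "encoding_map"))
  cols <- list()
  for (v in names(map$variables)) {
    sc <- map$variables[[v]]
    if (sc$type == "numeric") {
      z <- (cohort[[v]] - sc$mean) / sc$sd
      cols[[v]] <- matrix(z, ncol = 1, dimnames = list(NULL, v))
    } else {
      vals <- as.character(cohort[[v]])
      bad <- setdiff(unique(vals), sc$levels)
      if (length(bad)) {
        stop(sprintf("unseen category for variable '%s': %s", v,
                     paste(bad, collapse = ", ")))
      }
      idx <- match(vals, sc$levels)
      block <- matrix(0, nrow(cohort), length(sc$levels),
                      dimnames = list(NULL, paste(v, sc$levels, sep = ".")))
      block[cbind(seq_len(nrow(cohort)), idx)] <- 1
      cols[[v]] <- block
    }
  }
  list(x = do.call(cbind, cols), map = map)
}

# fixed variable order and schemes of the GAN encoding
fit_encoding_map <- function(cohort) {
  pop_sd <- function(x) sqrt(mean((x - mean(x))^2))
  num_scheme <- function(x, name) {
    s <- pop_sd(x)
    if (s == 0) {
      warning(sprintf("zero-variance numeric column '%s'; sd fallback to 1",
                      name))
      s <- 1
    }
    list(type = "numeric", mean = mean(x), sd = s)
  }
  vars <- list(
    age = num_scheme(cohort$age, "age"),
    gender = list(type = "categorical", levels = gender_levels()),
    site = list(type = "categorical", levels = site_levels()),
    metastatic = list(type = "categorical", levels = c("0", "1")),
    bone_mets = list(type = "categorical", levels = c("0", "1")),
    btcp = list(type = "categorical", levels = c("0", "1")),
    neuropathic = list(type = "categorical", levels = c("0", "1")),
    ecog = list(type = "categorical", levels = as.character(0:4)),
    med_gt60 = list(type = "categorical", levels = c("0", "1")),
    n_televisits = num_scheme(cohort$n_televisits, "n_televisits")
  )
  structure(list(variables = vars), class = "encoding_map")
}

# block layout of an encoding map: start/end column per variable
encoding_blocks <- function(map) {
  widths <- vapply(map$variables, function(sc) {
    if (sc$type == "numeric") 1L else length(sc$levels)
  }, integer(1))
  ends <- cumsum(widths)
  starts <- ends - widths + 1L
  data.frame(variable = names(widths), start = starts, end = ends,
             type = vapply(map$variables, `[[`, "", "type"),
             row.names = NULL)
}

encoding_width <- function(map) {
  b <- encoding_blocks(map)
  b$end[nrow(b)]
}

#' Decode an encoded matrix back into patient records
#'
#' Inverse of [encode_cohort()]: each categorical block is decoded by
#' arg-max, numeric columns are de-standardized; `age` is rounded to the
#' nearest integer and clipped to \[18, 95\], `n_televisits` rounded and
#' clipped to at least 1. `decode_matrix(encode_cohort(c)$x, map)`
#' reproduces `c`'s feature columns exactly.
#'
#' @param x numeric matrix with as many columns as the map's encoding width.
#' @param map the `encoding_map` used to encode.
#' @return a data frame with the decoded feature columns (no `patient_id`
#'   or `outcome`).
#' @export
decode_matrix <- function(x, map) {
  stopifnot(inherits(map, "encoding_map"))
  if (ncol(x) != encoding_width(map)) {
    stop(sprintf("matrix has %d columns but the encoding map expects %d",
                 ncol(x), encoding_width(map)))
  }
  blocks <- encoding_blocks(map)
  out <- list()
  for (i in seq_len(nrow(blocks))) {
    v <- blocks$variable[i]
    sc <- map$variables[[v]]
    sub <- x[, blocks$start[i]:blocks$end[i], drop = FALSE]
    if (sc$type == "numeric") {
      val <- drop(sub) * sc$sd + sc$mean
      if (v == "age") {
        val <- as.integer(pmin(pmax(round(val), 18L), 95L))
      } else if (v == "n_televisits") {
        val <- as.integer(pmax(round(val), 1L))
      }
      out[[v]] <- val
    } else {
      lev <- sc$levels[max.col(sub, ties.method = "first")]
      out[[v]] <- switch(v,
        gender = factor(lev, levels = gender_levels()),
        site = factor(lev, levels = site_levels()),
        as.integer(lev))
    }
  }
  as.data.frame(out, check.names = FALSE)
}

#' Random train/test split indices
#'
#' Uniformly random permutation split: the training set receives
#' `floor(ratio * n)` rows, the remainder goes to the test set.
#' Deterministic for a given seed.
#'
#' @param n number of rows (at least 2).
#' @param ratio training fraction, strictly between 0 and 1.
#' @param seed integer seed.
#' @return a `split_indices` object with sorted `train` and `test` index
#'   vectors.
#' @export
split_indices <- function(n, ratio, seed) {
  if (n < 2) stop("need at least 2 rows to split")
  if (ratio <= 0 || ratio >= 1) stop("ratio must be strictly in (0, 1)")
  n_train <- floor(ratio * n)
  if (n_train < 1 || n_train >= n) stop("degenerate split: empty partition")
  perm <- with_seed(seed, sample.int(n))
  structure(list(train = sort(perm[seq_len(n_train)]),
                 test = sort(perm[(n_train + 1):n]),
                 ratio = ratio, seed = seed),
            class = "split_indices")
}

#' @exportS3Method
print.split_indices <- function(x, ...) {
  cat(sprintf("Split: %d train / %d test (ratio %.2f, seed %d)\n",
              length(x$train), length(x$test), x$ratio, x$seed))
  invisible(x)
}

#' Serialize / deserialize an encoding map as JSON
#'
#' @param map an `encoding_map`.
#' @param path file path.
#' @return `read_encoding_map` returns an `encoding_map`; `write_encoding_map`
#'   returns `path` invisibly.
#' @export
write_encoding_map <- function(map, path) {
  jsonlite::write_json(unclass(map), path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' @rdname write_encoding_map
#' @export
read_encoding_map <- function(path) {
  obj <- jsonlite::read_json(path, simplifyVector = TRUE)
  obj$variables <- lapply(obj$variables, function(sc) {
    if (sc$type == "categorical") sc$levels <- as.character(sc$levels)
    sc
  })
  structure(obj, class = "encoding_map")
}
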