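#' Clinical data tables with an explicit missingness mask
#'
#' A \code{clinical_table} couples a schema-typed grid of cell values with a
#' logical missingness mask of the same shape. The mask — not a sentinel
#' value — is the single source of truth for which cells are missing; label
#' cells are never allowed to be missing.
#'
#' @param values a data.frame whose columns match the schema (numeric columns
#'   numeric, binary/categorical columns character).
#' @param schema a \code{\link{feature_schema}}.
#' @param mask logical matrix, same dimensions as \code{values}; \code{TRUE}
#'   marks a missing cell. Defaults to all observed.
#' @return an object of class \code{"clinical_table"}.
#' @export
clinical_table <- function(values, schema, mask = NULL) {
  stopifnot(inherits(schema, "feature_schema"), is.data.frame(values))
  if (!identical(names(values), schema$names))
    stop("schema error: table columns ", paste(names(values), collapse = ","),
         " do not match schema columns")
  n <- nrow(values)
  if (is.null(mask)) mask <- matrix(FALSE, n, length(schema$names))
  if (!is.logical(mask) || !all(dim(mask) == c(n, length(schema$names))))
    stop("mask shape does not match value grid")
  colnames(mask) <- schema$names
  tab <- structure(list(values = values, schema = schema, mask = mask),
                   class = "clinical_table")
  validate_table(tab)
  tab
}

validate_table <- function(tab) {
  sch <- tab$schema
  if (any(tab$mask[, sch$label_column]))
    stop("validation error: missing label cell (column '",
         sch$label_column, "')")
  for (nm in sch$names) {
    v <- tab$values[[nm]]
    obs <- !tab$mask[, nm]
    if (sch$kinds[[nm]] == "numeric") {
      if (!is.numeric(v))
        stop("validation error: column '", nm, "' must be numeric")
      if (any(obs & !is.finite(v)))
        stop("validation error: non-finite observed value in column '", nm, "'")
    } else {
      bad <- which(obs & !(as.character(v) %in% sch$levels[[nm]]))
      if (length(bad))
        stop("validation error: value '", v[bad[1]], "' in column '", nm,
             "' row ", bad[1], " is not a declared level")
    }
  }
  invisible(tab)
}

#' @export
print.clinical_table <- function(x, ...) {
  cat("Clinical table:", nrow(x$values), "rows x", ncol(x$values),
      "columns;", sum(x$mask), "missing cells\n")
  lab <- x$values[[x$schema$label_column]]
  tb <- table(lab)
  cat("  label '", x$schema$label_column, "': ",
      paste(names(tb), tb, sep = "=", collapse = ", "), "\n", sep = "")
  invisible(x)
}

#' @export
dim.clinical_table <- function(x) dim(x$values)

is_missing_token <- function(x) {
  x == "" | tolower(x) == "na"
}

#' Read a clinical CSV against a schema
#'
#' Parses an RFC-4180 CSV with a mandatory header row. Cells equal to the
#' empty string or \code{"NA"} (case-insensitive) are flagged missing in the
#' mask; every other cell is validated against the schema (numeric columns
#' must parse, binary/categorical values must be declared levels, labels must
#' be present).
#'
#' @param path path to a CSV file.
#' @param schema a \code{\link{feature_schema}} whose column names must match
#'   the header exactly.
#' @return a \code{\link{clinical_table}}.
#' @export
load_table <- function(path, schema) {
  if (!file.exists(path)) stop("file not found: ", path)
  raw <- utils::read.csv(path, colClasses = "character", check.names = FALSE,
                         na.strings = character(0))
  if (!identical(names(raw), schema$names))
    stop("schema error: CSV header (", paste(names(raw), collapse = ","),
         ") does not match schema")
  n <- nrow(raw)
  mask <- matrix(FALSE, n, length(schema$names),
                 dimnames = list(NULL, schema$names))
  vals <- raw
  for (nm in schema$names) {
    cell <- raw[[nm]]
    miss <- is_missing_token(cell)
    mask[, nm] <- miss
    if (schema$kinds[[nm]] == "numeric") {
      num <- suppressWarnings(as.numeric(cell))
      bad <- which(!miss & is.na(num))
      if (length(bad))
        stop("validation error: non-numeric value '", cell[bad[1]],
             "' in column '", nm, "' row ", bad[1])
      num[miss] <- NA_real_
      vals[[nm]] <- num
    } else {
      cell[miss] <- NA_character_
      vals[[nm]] <- cell
    }
  }
  clinical_table(vals, schema, mask)
}

#' Write a clinical table to CSV
#'
#' Missing cells are written as empty strings, so
#' \code{load_table(write_table(x))} round-trips both values and mask.
#'
#' @param table a \code{\link{clinical_table}}.
#' @param path output CSV path.
#' @return \code{path}, invisibly.
#' @export
write_table <- function(table, path) {
  out <- table$values
  for (nm in names(out)) {
    cell <- as.character(out[[nm]])
    cell[table$mask[, nm]] <- ""
    cell[is.na(cell)] <- ""
    out[[nm]] <- cell
  }
  utils::write.csv(out, path, row.names = FALSE, quote = TRUE)
  invisible(path)
}

#' Encode a clinical table to a numeric matrix
#'
#' Numeric columns are min-max scaled to [0,1] using observed values only;
#' binary columns map their two declared levels to 0/1; categorical columns
#' are one-hot in declared-level order (one input per category, so the
#' dimensionality of the problem space tracks the category count). Missing
#' source cells propagate their mask flag to every derived column and carry a
#' placeholder 0 — the mask, not the placeholder, carries the information.
#'
#' When \code{map} (a frozen encoding map from a training table) is supplied,
#' its min/max are reused and scaled values are clipped to [0,1], so no test
#' information leaks into the scaling.
#'
#' @param table a \code{\link{clinical_table}}.
#' @param map optional encoding map from a previous \code{encode_table} call.
#' @return an object of class \code{"encoded_matrix"}: list with \code{X}
#'   (n x d matrix), \code{mask} (n x d logical), \code{map}, \code{y}
#'   (0/1 label vector), \code{ids}, \code{schema}.
#' @export
encode_table <- function(table, map = NULL) {
  sch <- table$schema
  feats <- feature_columns(sch)
  build_map <- is.null(map)
  if (build_map) {
    map <- list()
    for (nm in feats) {
      kind <- sch$kinds[[nm]]
      if (kind == "numeric") {
        obs <- table$values[[nm]][!table$mask[, nm]]
        if (!length(obs)) stop("column '", nm, "' has no observed cells")
        mn <- min(obs); mx <- max(obs)
        constant <- mx <= mn
        if (constant)
          warning("numeric column '", nm,
                  "' has zero observed range; encoded as constant 0.5")
        map[[nm]] <- list(kind = "numeric", min = mn, max = mx,
                          constant = constant)
      } else if (kind == "binary") {
        map[[nm]] <- list(kind = "binary", levels = sch$levels[[nm]])
      } else {
        map[[nm]] <- list(kind = "categorical", levels = sch$levels[[nm]])
      }
    }
  }
  cols <- list(); mcols <- list(); cnames <- character(0)
  for (nm in feats) {
    mp <- map[[nm]]
    if (is.null(mp))
      stop("structural error: column '", nm, "' is not in the encoding map")
    miss <- table$mask[, nm]
    if (mp$kind == "numeric") {
      v <- table$values[[nm]]
      enc <- if (mp$constant) rep(0.5, length(v))
        else pmin(1, pmax(0, (v - mp$min) / (mp$max - mp$min)))
      enc[miss] <- 0
      cols[[nm]] <- matrix(enc, ncol = 1)
      mcols[[nm]] <- matrix(miss, ncol = 1)
      cnames <- c(cnames, nm)
    } else if (mp$kind == "binary") {
      v <- as.character(table$values[[nm]])
      enc <- as.numeric(match(v, mp$levels) - 1L)
      enc[miss] <- 0
      cols[[nm]] <- matrix(enc, ncol = 1)
      mcols[[nm]] <- matrix(miss, ncol = 1)
      cnames <- c(cnames, nm)
    } else {
      v <- as.character(table$values[[nm]])
      idx <- match(v, mp$levels)
      onehot <- matrix(0, nrow(table$values), length(mp$levels))
      ok <- which(!miss)
      onehot[cbind(ok, idx[ok])] <- 1
      cols[[nm]] <- onehot
      mcols[[nm]] <- matrix(miss, nrow(table$values), length(mp$levels))
      cnames <- c(cnames, paste0(nm, "=", mp$levels))
    }
  }
  X <- do.call(cbind, cols)
  M <- do.call(cbind, mcols)
  colnames(X) <- cnames; colnames(M) <- cnames
  # record the derived-column span of every source column
  start <- 1L
  for (nm in feats) {
    w <- ncol(cols[[nm]])
    map[[nm]]$cols <- seq.int(start, start + w - 1L)
    start <- start + w
  }
  ylv <- sch$levels[[sch$label_column]]
  y <- as.integer(match(as.character(table$values[[sch$label_column]]), ylv) - 1L)
  ids <- if (!is.null(sch$id_column)) table$values[[sch$id_column]] else NULL
  id_mask <- if (!is.null(sch$id_column)) table$mask[, sch$id_column] else NULL
  structure(list(X = X, mask = M, map = map, y = y, ids = ids,
                 id_mask = id_mask, schema = sch),
            class = "encoded_matrix")
}

# Which encoded columns carry continuous values (identity output / squared
# error) as opposed to binary or one-hot indicators (sigmoid / cross-entropy).
continuous_cols <- function(enc) {
  idx <- logical(ncol(enc$X))
  for (nm in names(enc$map))
    if (enc$map[[nm]]$kind == "numeric" && !isTRUE(enc$map[[nm]]$constant))
      idx[enc$map[[nm]]$cols] <- TRUE
  idx
}

#' Decode an encoded matrix back to a clinical table
#'
#' Inverse of \code{\link{encode_table}}: numeric columns are inverse
#' min-max scaled, binary columns thresholded at 0.5, one-hot groups decoded
#' by arg-max. Cells whose mask flag is still set stay missing in the output.
#'
#' @param enc an \code{"encoded_matrix"}.
#' @return a \code{\link{clinical_table}}.
#' @export
decode_matrix <- function(enc) {
  sch <- enc$schema
  d <- sum(vapply(enc$map, function(m) length(m$cols), integer(1)))
  if (ncol(enc$X) != d)
    stop("structural error: matrix width ", ncol(enc$X),
         " does not match encoding map width ", d)
  n <- nrow(enc$X)
  vals <- vector("list", length(sch$names)); names(vals) <- sch$names
  mask <- matrix(FALSE, n, length(sch$names),
                 dimnames = list(NULL, sch$names))
  for (nm in names(enc$map)) {
    mp <- enc$map[[nm]]
    miss <- enc$mask[, mp$cols[1]]
    mask[, nm] <- miss
    if (mp$kind == "numeric") {
      v <- if (isTRUE(mp$constant)) rep(mp$min, n)
        else enc$X[, mp$cols] * (mp$max - mp$min) + mp$min
      v[miss] <- NA_real_
      vals[[nm]] <- v
    } else if (mp$kind == "binary") {
      v <- mp$levels[as.integer(enc$X[, mp$cols] >= 0.5) + 1L]
      v[miss] <- NA_character_
      vals[[nm]] <- v
    } else {
      v <- mp$levels[max.col(enc$X[, mp$cols, drop = FALSE], "first")]
      v[miss] <- NA_character_
      vals[[nm]] <- v
    }
  }
  ylv <- sch$levels[[sch$label_column]]
  vals[[sch$label_column]] <- ylv[enc$y + 1L]
  if (!is.null(sch$id_column)) {
    idv <- enc$ids
    if (is.null(idv)) idv <- rep(NA_real_, n)
    vals[[sch$id_column]] <- idv
    if (!is.null(enc$id_mask)) mask[, sch$id_column] <- enc$id_mask
  }
  clinical_table(as.data.frame(vals[sch$names], check.names = FALSE,
                               stringsAsFactors = FALSE), sch, mask)
}

#' Stratified train/test split
#'
#' Splits row indices so that each label class contributes
#' \code{round(n_class * test_fraction)} rows to the test set — the per-class
#' test proportion is within one sample of the requested fraction — and the
#' split is deterministic given the seed.
#'
#' @param table a \code{\link{clinical_table}}.
#' @param test_fraction fraction of rows held out, strictly between 0 and 1.
#' @param seed integer seed.
#' @return list with integer vectors \code{train} and \code{test}.
#' @export
stratified_split <- function(table, test_fraction, seed) {
  stopifnot(test_fraction > 0, test_fraction < 1)
  y <- as.character(table$values[[table$schema$label_column]])
  counts <- table(y)
  if (any(counts < 2))
    stop("stratified_split: class '", names(counts)[counts < 2][1],
         "' has fewer than 2 members")
  test <- integer(0)
  with_seed(seed, {
    for (cl in sort(names(counts))) {
      idx <- which(y == cl)
      k <- round(length(idx) * test_fraction)
      test <- c(test, sample(idx, k))
    }
  })
  test <- sort(test)
  list(train = setdiff(seq_along(y), test), test = test)
}

#' Subset a clinical table by row indices
#'
#' Keeps the schema and mask aligned, and carries any hidden-truth
#' attribute along so imputation scoring still works on the subset.
#'
#' @param table a \code{\link{clinical_table}}.
#' @param rows integer row indices.
#' @return a \code{\link{clinical_table}}.
#' @export
subset_table <- function(table, rows) {
  tab <- clinical_table(table$values[rows, , drop = FALSE],
                        table$schema,
                        table$mask[rows, , drop = FALSE])
  if (!is.null(attr(table, "hidden_truth"))) {
    ht <- attr(table, "hidden_truth")
    attr(tab, "hidden_truth") <- ht[rows, , drop = FALSE]
  }
  tab
}
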