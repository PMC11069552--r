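#' Declare the column layout of a clinical table
#'
#' A feature schema fixes, for every column of a clinical record table, its
#' name, its kind (\code{"numeric"}, \code{"binary"} or \code{"categorical"})
#' and, for binary/categorical columns, the ordered set of admissible levels.
#' The level order is part of the schema: binary columns encode
#' \code{first level -> 0, second level -> 1}, and one-hot columns are laid
#' out in declared-level order, so the schema alone determines the encoding.
#'
#' @param columns a list of column descriptors, each a list with entries
#'   \code{name}, \code{kind} and (for non-numeric kinds) \code{levels}.
#' @param label_column name of the binary outcome column.
#' @param id_column optional name of a row-identifier column, excluded from
#'   encoding and modelling.
#' @return an object of class \code{"feature_schema"}.
#' @examples
#' sch <- feature_schema(
#'   list(list(name = "age", kind = "numeric"),
#'        list(name = "hypertension", kind = "binary", levels = c("0", "1")),
#'        list(name = "stroke", kind = "binary", levels = c("0", "1"))),
#'   label_column = "stroke")
#' @export
feature_schema <- function(columns, label_column, id_column = NULL) {
  stopifnot(is.list(columns), length(columns) >= 1L)
  nms <- vapply(columns, function(cl) cl$name, character(1))
  if (anyDuplicated(nms))
    stop("schema error: duplicate column names: ",
         paste(unique(nms[duplicated(nms)]), collapse = ", "))
  kinds <- vapply(columns, function(cl) cl$kind, character(1))
  bad <- setdiff(kinds, c("numeric", "binary", "categorical"))
  if (length(bad)) stop("schema error: unknown column kind: ", bad[1])
  levels <- lapply(columns, function(cl) {
    if (cl$kind == "numeric") return(NULL)
    lv <- as.character(cl$levels)
    if (cl$kind == "binary" && length(lv) != 2L)
      stop("schema error: binary column '", cl$name, "' needs exactly 2 levels")
    if (cl$kind == "categorical" && length(lv) < 2L)
      stop("schema error: categorical column '", cl$name, "' needs >= 2 levels")
    if (anyDuplicated(lv))
      stop("schema error: duplicate levels in column '", cl$name, "'")
    lv
  })
  names(levels) <- nms
  if (!label_column %in% nms)
    stop("schema error: label column '", label_column, "' not declared")
  if (kinds[match(label_column, nms)] != "binary")
    stop("schema error: label column must be binary")
  if (!is.null(id_column)) {
    if (!id_column %in% nms)
      stop("schema error: id column '", id_column, "' not declared")
    if (id_column == label_column)
      stop("schema error: id column cannot be the label column")
  }
  structure(
    list(names = nms, kinds = stats::setNames(kinds, nms), levels = levels,
         label_column = label_column, id_column = id_column),
    class = "feature_schema")
}

#' @export
print.feature_schema <- function(x, ...) {
  cat("Feature schema:", length(x$names), "columns\n")
  for (nm in x$names) {
    tag <- if (nm == x$label_column) " [label]"
      else if (!is.null(x$id_column) && nm == x$id_column) " [id]" else ""
    lv <- if (x$kinds[[nm]] == "numeric") "" else
      paste0(" {", paste(x$levels[[nm]], collapse = ", "), "}")
    cat("  ", nm, ": ", x$kinds[[nm]], lv, tag, "\n", sep = "")
  }
  invisible(x)
}

#' Names of the feature columns (non-label, non-id) of a schema
#' @param schema a \code{feature_schema}.
#' @return character vector of feature column names in schema order.
#' @export
feature_columns <- function(schema) {
  drop <- c(schema$label_column, schema$id_column)
  setdiff(schema$names, drop)
}

#' The stroke cohort schema
#'
#' The default clinical schema used throughout the package: a de-identified
#' stroke-risk record with demographic, comorbidity and lifestyle attributes
#' and a binary stroke outcome (patient id; gender; age in years;
#' hypertension and heart-disease flags; marital status; work type;
#' residence; average blood glucose in mg/dL; body-mass index; smoking
#' status; stroke label).
#'
#' @return a \code{feature_schema}.
#' @export
stroke_schema <- function() {
  feature_schema(
    list(
      list(name = "id", kind = "numeric"),
      list(name = "gender", kind = "binary", levels = c("Female", "Male")),
      list(name = "age", kind = "numeric"),
      list(name = "hypertension", kind = "binary", levels = c("0", "1")),
      list(name = "heart_disease", kind = "binary", levels = c("0", "1")),
      list(name = "ever_married", kind = "binary", levels = c("No", "Yes")),
      list(name = "work_type", kind = "categorical",
           levels = c("Govt_job", "Never_worked", "Private", "Self_employed")),
      list(name = "residence", kind = "binary", levels = c("Rural", "Urban")),
      list(name = "avg_glucose", kind = "numeric"),
      list(name = "bmi", kind = "numeric"),
      list(name = "smoking_status", kind = "categorical",
           levels = c("formerly_smoked", "never_smoked", "smokes", "unknown")),
      list(name = "stroke", kind = "binary", levels = c("0", "1"))
    ),
    label_column = "stroke", id_column = "id")
}
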