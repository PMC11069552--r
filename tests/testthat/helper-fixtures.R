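# Shared fixtures: tiny schemas and tables built in code.

tiny_schema <- function() {
  feature_schema(
    list(list(name = "age", kind = "numeric"),
         list(name = "gender", kind = "binary", levels = c("F", "M")),
         list(name = "work", kind = "categorical",
              levels = c("home", "office", "field")),
         list(name = "sick", kind = "binary", levels = c("0", "1"))),
    label_column = "sick")
}

tiny_table <- function() {
  clinical_table(
    data.frame(age = c(2, 4, 6), gender = c("F", "M", "F"),
               work = c("home", "field", "office"),
               sick = c("0", "1", "0"), stringsAsFactors = FALSE),
    tiny_schema())
}

# schema of d numeric features for feature-selection tests
numeric_schema <- function(d) {
  feature_schema(
    c(lapply(seq_len(d), function(j)
        list(name = sprintf("x%02d", j), kind = "numeric")),
      list(list(name = "disease", kind = "binary", levels = c("0", "1")))),
    label_column = "disease")
}

# random mixed-type schema for property tests
random_schema <- function(seed) {
  set.seed(seed)
  ncols <- sample(2:5, 1)
  cols <- lapply(seq_len(ncols), function(j) {
    kind <- sample(c("numeric", "binary", "categorical"), 1)
    if (kind == "numeric") list(name = paste0("c", j), kind = kind)
    else if (kind == "binary")
      list(name = paste0("c", j), kind = kind, levels = c("a", "b"))
    else list(name = paste0("c", j), kind = kind,
              levels = paste0("l", seq_len(sample(2:4, 1))))
  })
  cols <- c(cols, list(list(name = "y", kind = "binary",
                            levels = c("0", "1"))))
  feature_schema(cols, label_column = "y")
}

random_table <- function(schema, n, missing_rate = 0, seed = 1) {
  set.seed(seed)
  vals <- lapply(schema$names, function(nm) {
    if (schema$kinds[[nm]] == "numeric") round(runif(n, -5, 5), 3)
    else sample(schema$levels[[nm]], n, replace = TRUE)
  })
  names(vals) <- schema$names
  tab <- clinical_table(as.data.frame(vals, stringsAsFactors = FALSE), schema)
  if (missing_rate > 0)
    tab <- inject_missingness(tab, missing_rate, seed = seed + 1)
  tab
}

# tiny layered DAG generator for water-drop oracle tests
random_layered_graph <- function(seed) {
  set.seed(seed)
  nl <- sample(2:3, 1)
  sizes <- sample(1:2, nl, replace = TRUE)
  id <- 0
  layers <- lapply(sizes, function(k) {
    v <- paste0("n", id + seq_len(k)); id <<- id + k; v
  })
  layers <- c(list("S"), layers, list("T"))
  e <- NULL
  for (l in seq_len(length(layers) - 1)) for (fr in layers[[l]]) {
    tos <- layers[[l + 1]]
    tos <- tos[sample(length(tos), min(length(tos), sample(1:3, 1)))]
    for (to in tos)
      e <- rbind(e, data.frame(from = fr, to = to,
                               cost = round(runif(1, 1, 10), 2)))
  }
  iwd_graph(e, "S", "T")
}

path_cost <- function(graph, p) {
  s <- 0
  for (k in seq_len(length(p) - 1))
    s <- s + graph$edges$cost[graph$edges$from == p[k] &
                              graph$edges$to == p[k + 1]]
  s
}

brute_force_optimum <- function(graph) {
  min(vapply(enumerate_paths(graph), function(p) path_cost(graph, p),
             numeric(1)))
}
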