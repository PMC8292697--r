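# Programmatic fixtures shared across test files.

FOR_UID <- rtqa_uid("test-frame")

small_grid <- function(field = dose_field_spec("UNIFORM", level = 20),
                       origin = c(-12, -12, -12), spacing = c(1, 1, 1),
                       shape = c(25, 25, 25)) {
  make_dose_grid(field, origin = origin, spacing = spacing, shape = shape,
                 frame_of_reference = FOR_UID)
}

# random phantom whose z extent stays inside even the short acceptance grid
# (planes spanning -7..7 mm)
random_phantom <- function(i) {
  shape <- c("BOX", "CYLINDER", "SPHERE")[(i %% 3) + 1]
  center <- c(runif(2, -2.5, 2.5), runif(1, -2, 2))
  dims <- switch(shape,
    BOX = c(runif(2, 6, 16), runif(1, 6, 9)),
    CYLINDER = c(runif(1, 3, 8), runif(1, 6, 9)),
    SPHERE = runif(1, 3, 4.5))
  make_structure(phantom_spec(shape, center, dims, slice_thickness = 2,
                              polygon_vertices = 12L),
                 name = paste0("s", i), roi_number = i)
}

random_field <- function(i) {
  switch((i %% 3) + 1,
    dose_field_spec("UNIFORM", level = runif(1, 5, 70)),
    dose_field_spec("LINEAR_X", gradient = runif(1, 0.05, 0.6),
                    intercept = runif(1, 0, 10)),
    dose_field_spec("SPHERICAL_FALLOFF", center = runif(3, -4, 4),
                    peak = runif(1, 40, 75), radius = runif(1, 25, 60)))
}

# random decision tree over categorical features f1..f8 (values a/b/c)
random_measure <- function(id, n_features = 4, max_depth = 4) {
  feats <- paste0("f", seq_len(n_features))
  counter <- 0
  nodes <- list()
  new_leaf <- function() {
    counter <<- counter + 1
    nid <- paste0("n", counter)
    nodes[[nid]] <<- list(result = sample(c("PASS", "FAIL",
                                            "NOT_APPLICABLE"), 1))
    nid
  }
  build <- function(depth) {
    if (depth >= max_depth || runif(1) < 0.3) return(new_leaf())
    counter <<- counter + 1
    nid <- paste0("n", counter)
    op <- sample(c("EQ", "NE", "IN", "EXISTS"), 1)
    node <- list(field = sample(feats, 1), op = op)
    if (op == "IN") node$value <- as.list(sample(c("a", "b", "c"),
                                                 sample(1:2, 1)))
    else if (op != "EXISTS") node$value <- sample(c("a", "b", "c"), 1)
    nodes[[nid]] <<- node  # reserve slot before recursing
    t_branch <- build(depth + 1)
    f_branch <- build(depth + 1)
    node$true <- t_branch; node$false <- f_branch
    nodes[[nid]] <<- node
    nid
  }
  root <- build(0)
  list(measure_id = id, title = id, category = "EXPECTED",
       root = root, nodes = nodes)
}

# all assignments of values (a/b/c/missing) to the features of a measure
feature_assignments <- function(measure, n_features = 4) {
  used <- unique(stats::na.omit(vapply(measure$nodes, function(n)
    if (is.null(n$result)) n$field else NA_character_, character(1))))
  if (!length(used)) return(list(list()))
  vals <- list("a", "b", "c", NULL)
  grids <- do.call(expand.grid, c(rep(list(1:4), length(used)),
                                  list(KEEP.OUT.ATTRS = FALSE)))
  lapply(seq_len(nrow(grids)), function(r) {
    f <- list()
    for (j in seq_along(used)) {
      v <- vals[[grids[r, j]]]
      if (!is.null(v)) f[[used[j]]] <- v
    }
    f
  })
}

read_text <- function(path) readChar(path, file.size(path))
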