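#' Load and validate a parcel node table
#'
#' A node table is a TSV with columns `index` (0-based), `name` (AAL-style
#' label), `x`, `y`, `z` (MNI-style mm coordinates) and `is_seed`. The
#' canonical table has 92 rows (90 AAL parcels plus the two accumbens
#' nuclei) and exactly 13 seed regions.
#'
#' @param path Path to the TSV file.
#' @param canonical Enforce the canonical 92-row / 13-seed shape.
#' @return Validated `data.frame`.
#' @export
load_node_table <- function(path, canonical = FALSE) {
  tab <- utils::read.delim(path, stringsAsFactors = FALSE)
  req <- c("index", "name", "x", "y", "z", "is_seed")
  missing_cols <- setdiff(req, names(tab))
  if (length(missing_cols) > 0) {
    stop("node table is missing column(s): ",
         paste(missing_cols, collapse = ", "), call. = FALSE)
  }
  if (anyDuplicated(tab$name)) {
    stop("node table has duplicate names: ",
         paste(unique(tab$name[duplicated(tab$name)]), collapse = ", "),
         call. = FALSE)
  }
  tab$is_seed <- as.logical(tab$is_seed)
  if (any(!is.finite(tab$x) | !is.finite(tab$y) | !is.finite(tab$z))) {
    stop("node table has non-finite coordinates", call. = FALSE)
  }
  if (canonical) {
    if (nrow(tab) != 92) {
      stop("canonical node table must have 92 rows, found ", nrow(tab),
           call. = FALSE)
    }
    if (sum(tab$is_seed) != 13) {
      stop("canonical node table must flag exactly 13 seeds, found ",
           sum(tab$is_seed), call. = FALSE)
    }
  }
  tab[, req]
}

#' The packaged canonical 92-node table
#'
#' 90 AAL parcels plus two accumbens nuclei with 13 seed regions flagged.
#' Node names follow the AAL convention; the centroid coordinates are
#' synthetic approximations shipped for layout and export only (the real
#' atlas is not distributed with the package). Users can substitute their
#' own table via [load_node_table()].
#'
#' @return `data.frame` of 92 nodes.
#' @export
megfc_node_table <- function() {
  load_node_table(system.file("extdata", "aal92_nodes_synthetic.tsv",
                              package = "megfc", mustWork = TRUE),
                  canonical = TRUE)
}

#' Write a node table to TSV
#'
#' @param tab Node table (`data.frame`).
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_node_table <- function(tab, path) {
  utils::write.table(tab, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Write / read a trial manifest as TSV
#'
#' @param manifest Manifest `data.frame` (see [build_paradigm()]).
#' @param path File path.
#' @return `write_manifest` returns `path` invisibly; `read_manifest` the
#'   `data.frame`.
#' @export
write_manifest <- function(manifest, path) {
  utils::write.table(manifest, path, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  invisible(path)
}

#' @rdname write_manifest
#' @export
read_manifest <- function(path) {
  m <- utils::read.delim(path, stringsAsFactors = FALSE)
  m$is_rest <- as.logical(m$is_rest)
  m
}

#' Write a labelled connectivity matrix to TSV
#'
#' @param M Matrix.
#' @param path Output path.
#' @param row_names,col_names Labels (defaults: `dimnames` or indices).
#' @return `path`, invisibly.
#' @export
write_matrix_tsv <- function(M, path, row_names = NULL, col_names = NULL) {
  if (is.null(row_names)) row_names <- rownames(M) %||% seq_len(nrow(M))
  if (is.null(col_names)) col_names <- colnames(M) %||% seq_len(ncol(M))
  df <- data.frame(node = row_names, M)
  names(df) <- c("node", col_names)
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Export an NBS component in BrainNet node/edge convention
#'
#' Writes `<prefix>.node` (columns: x y z color size label, one row per
#' component node) and `<prefix>.edge` (square symmetric weight matrix over
#' the component nodes). Node size is the node's degree within the
#' component; empty components produce header-only files.
#'
#' @param component One component from [extract_components()] /
#'   [nbs_permutation_test()].
#' @param node_table Node table covering all component nodes.
#' @param prefix Output path prefix.
#' @param weights Optional symmetric matrix of edge weights over all
#'   parcels; defaults to weight 1 per component edge.
#' @return Invisible character vector of the two file paths.
#' @export
export_network <- function(component, node_table, prefix, weights = NULL) {
  node_path <- paste0(prefix, ".node")
  edge_path <- paste0(prefix, ".edge")
  nodes <- if (is.null(component) || length(component) == 0) integer(0) else component$nodes
  if (length(nodes) > 0 && any(nodes > nrow(node_table))) {
    stop("component references node index outside the node table",
         call. = FALSE)
  }
  header <- "# x\ty\tz\tcolor\tsize\tlabel"
  if (length(nodes) == 0) {
    writeLines(header, node_path)
    writeLines("# empty component", edge_path)
    return(invisible(c(node_path, edge_path)))
  }
  nt <- node_table[nodes, , drop = FALSE]
  deg <- vapply(nodes, function(v) sum(component$edges == v), integer(1))
  lines <- sprintf("%g\t%g\t%g\t%d\t%d\t%s", nt$x, nt$y, nt$z, 1L, deg,
                   nt$name)
  writeLines(c(header, lines), node_path)
  k <- length(nodes)
  E <- matrix(0, k, k)
  for (r in seq_len(nrow(component$edges))) {
    a <- match(component$edges[r, 1], nodes)
    b <- match(component$edges[r, 2], nodes)
    w <- if (is.null(weights)) 1 else weights[component$edges[r, 1],
                                              component$edges[r, 2]]
    E[a, b] <- w
    E[b, a] <- w
  }
  utils::write.table(E, edge_path, sep = "\t", quote = FALSE,
                     row.names = FALSE, col.names = FALSE)
  invisible(c(node_path, edge_path))
}

#' Re-import an exported BrainNet node/edge pair
#'
#' @param prefix Path prefix used by [export_network()].
#' @param node_table Node table to map labels back to indices.
#' @return List with `nodes` (indices) and `edges` (m x 2 index matrix).
#' @export
read_network <- function(prefix, node_table) {
  node_lines <- readLines(paste0(prefix, ".node"))
  node_lines <- node_lines[!startsWith(node_lines, "#")]
  if (length(node_lines) == 0) {
    return(list(nodes = integer(0), edges = matrix(0L, 0, 2)))
  }
  parts <- strsplit(node_lines, "\t")
  labels <- vapply(parts, function(p) p[[6]], character(1))
  nodes <- match(labels, node_table$name)
  E <- as.matrix(utils::read.table(paste0(prefix, ".edge"), sep = "\t",
                                   comment.char = "#"))
  idx <- which(upper.tri(E) & E != 0, arr.ind = TRUE)
  edges <- cbind(i = nodes[idx[, 1]], j = nodes[idx[, 2]])
  edges <- edges[order(pmin(edges[, 1], edges[, 2]),
                       pmax(edges[, 1], edges[, 2])), , drop = FALSE]
  edges <- cbind(i = pmin(edges[, 1], edges[, 2]),
                 j = pmax(edges[, 1], edges[, 2]))
  list(nodes = sort(nodes), edges = edges)
}

#' Load a pipeline configuration from a YAML file
#'
#' Keys mirror the arguments of [simulation_config()], [paradigm_spec()]
#' and [run_pipeline()]; unknown keys raise an error. Thresholds and counts
#' must be positive.
#'
#' @param path Path to the YAML file.
#' @return Named list of configuration values.
#' @export
load_pipeline_config <- function(path) {
  cfg <- yaml::read_yaml(path)
  known <- c("n_subjects_per_group", "n_parcels", "n_trials_per_condition",
             "n_rest_trials", "trial_duration_s", "sampling_rate_hz",
             "bands", "metrics", "epoch_s", "trim_s", "motion_threshold_mm",
             "min_trials", "aec_threshold", "wpli_threshold",
             "interaction_threshold", "n_permutations", "alpha", "seed",
             "leakage_mixing_strength", "noise_sd", "envelope_depth",
             "motion_median_mm", "planted", "use_sensors", "sensor_count",
             "artifact_components", "out_dir", "analyses")
  unknown <- setdiff(names(cfg), known)
  if (length(unknown) > 0) {
    stop("unknown configuration key(s): ", paste(unknown, collapse = ", "),
         call. = FALSE)
  }
  num_pos <- intersect(names(cfg),
                       c("aec_threshold", "wpli_threshold",
                         "interaction_threshold", "n_permutations",
                         "min_trials", "motion_threshold_mm"))
  for (k in num_pos) {
    if (!is.numeric(cfg[[k]]) || any(cfg[[k]] <= 0)) {
      stop("configuration key '", k, "' must be positive", call. = FALSE)
    }
  }
  cfg
}
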