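#' Recognised compartment kinds
#'
#' The segmentation vocabulary of the outer-retina scene: RPE cell body,
#' nucleus, apical microvilli, basal infold (sub-RPE) spaces, mitochondria,
#' photoreceptor outer segments and Bruch's membrane. `background` is
#' reserved for label 0 and never appears in a label table.
#'
#' @format A character vector.
#' @export
compartment_kinds <- c(
  "cell_body", "nucleus", "microvilli", "basal_infold_space",
  "mitochondrion", "outer_segment", "bruchs_membrane"
)

# compartments that make up the solid of a cell (everything but microvilli)
.cell_solid_kinds <- c("cell_body", "nucleus", "mitochondrion",
                       "basal_infold_space")

#' Build a label table
#'
#' Maps every positive label id occurring in a label volume to the cell it
#' belongs to and the compartment it represents. Several labels may map to
#' the same (cell, compartment) pair (e.g. the two nuclei of a bi-nucleate
#' cell); masks are then unions over the matching labels.
#'
#' @param label Integer vector of label ids (unique, positive; 0 forbidden).
#' @param cell Character vector of cell identifiers.
#' @param compartment Character vector; each entry one of
#'   [compartment_kinds].
#'
#' @return A tibble of class `label_table` with columns `label`, `cell`,
#'   `compartment`.
#' @examples
#' label_table(label = c(1, 2, 3),
#'             cell = c("cell_1", "cell_1", "cell_1"),
#'             compartment = c("cell_body", "nucleus", "microvilli"))
#' @export
label_table <- function(label = integer(), cell = character(),
                        compartment = character()) {
  label <- as.integer(label)
  if (anyNA(label) || any(label <= 0L)) {
    stop("label ids must be positive integers (0 is reserved for background)",
         call. = FALSE)
  }
  if (anyDuplicated(label)) stop("label ids must be unique", call. = FALSE)
  if (length(cell) != length(label) || length(compartment) != length(label)) {
    stop("label, cell and compartment must have equal length", call. = FALSE)
  }
  bad <- setdiff(unique(compartment), compartment_kinds)
  if (length(bad) > 0) {
    stop("unknown compartment kind(s): ", paste(bad, collapse = ", "),
         call. = FALSE)
  }
  out <- tibble::tibble(label = label, cell = as.character(cell),
                        compartment = as.character(compartment))
  class(out) <- c("label_table", class(out))
  out
}

#' Read a JSON label table
#'
#' Expects the schema
#' `{"labels": {"<id>": {"cell": "...", "compartment": "..."}},
#'   "spacing_nm": [dz, dy, dx]}`.
#' The `spacing_nm` entry is optional; when present it is attached as the
#' `spacing` attribute (a [voxel_spacing]).
#'
#' @param path Path to a JSON file.
#' @return A `label_table`, possibly with a `spacing` attribute.
#' @export
read_label_table <- function(path) {
  if (!file.exists(path)) stop("label table not found: ", path, call. = FALSE)
  j <- jsonlite::read_json(path)
  labs <- j$labels
  if (is.null(labs)) labs <- list()
  ids <- as.integer(names(labs))
  tab <- label_table(
    label = ids,
    cell = vapply(labs, function(e) as.character(e$cell), character(1)),
    compartment = vapply(labs, function(e) as.character(e$compartment),
                         character(1))
  )
  if (!is.null(j$spacing_nm)) {
    s <- as.numeric(unlist(j$spacing_nm))  # stored [dz, dy, dx]
    attr(tab, "spacing") <- voxel_spacing(dx = s[3], dy = s[2], dz = s[1])
  }
  tab
}

#' Write a label table to JSON
#'
#' @param table A `label_table`.
#' @param path Output path.
#' @param spacing Optional [voxel_spacing] recorded as `spacing_nm`
#'   (`[dz, dy, dx]`).
#' @return The path, invisibly.
#' @export
write_label_table <- function(table, path, spacing = NULL) {
  entries <- stats::setNames(
    lapply(seq_len(nrow(table)), function(i) {
      list(cell = table$cell[i], compartment = table$compartment[i])
    }),
    as.character(table$label)
  )
  out <- list(labels = entries)
  if (!is.null(spacing)) {
    stopifnot(is_voxel_spacing(spacing))
    out$spacing_nm <- c(spacing$dz, spacing$dy, spacing$dx)
  }
  jsonlite::write_json(out, path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}

# labels matching an optional (cell, compartment) filter
labels_for <- function(table, cell = NULL, compartment = NULL) {
  keep <- rep(TRUE, nrow(table))
  if (!is.null(cell)) keep <- keep & table$cell %in% cell
  if (!is.null(compartment)) keep <- keep & table$compartment %in% compartment
  table$label[keep]
}
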