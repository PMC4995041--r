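# Tissue-network JSON interchange (one document per network). Vertex indices
# are 0-based in the file, 1-based in memory; cell loops counterclockwise.

#' Write a tissue network to JSON
#'
#' @param net A [tissue_network()].
#' @param path Output file path.
#' @return Invisibly, `path`.
#' @export
write_tissue <- function(net, path) {
  doc <- list(
    parameters = net$params[c("K", "A0", "Gamma_bar", "Lambda0_bar")],
    vertices = unname(lapply(seq_len(nrow(net$vertices)),
                             function(i) as.numeric(net$vertices[i, ]))),
    bonds = unname(lapply(seq_len(nrow(net$bonds)), function(b) {
      list(v = as.integer(net$bonds[b, ] - 1L),
           tension_bar = net$bond_tension[b],
           ablated = net$bond_ablated[b])
    })),
    cells = unname(lapply(seq_along(net$cells), function(cc) {
      list(vertices = as.integer(net$cells[[cc]] - 1L),
           preferred_area = net$cell_prefarea[cc],
           clone = net$cell_clone[cc],
           compartment = if (is.na(net$cell_compartment[cc])) NULL
                         else net$cell_compartment[cc])
    })),
    metadata = net$metadata
  )
  json <- jsonlite::toJSON(doc, auto_unbox = TRUE, digits = NA, null = "null",
                           pretty = FALSE)
  writeLines(json, path)
  invisible(path)
}

#' Read a tissue network from JSON
#'
#' @param path Input file path.
#' @param strict Reject unknown fields (default `TRUE`).
#' @param validate Run [validate_tissue()] on the result (default `TRUE`).
#' @return A [tissue_network()].
#' @export
read_tissue <- function(path, strict = TRUE, validate = TRUE) {
  if (!file.exists(path)) stop("read_tissue: no such file: ", path)
  doc <- tryCatch(
    jsonlite::fromJSON(path, simplifyVector = FALSE),
    error = function(e) {
      stop(sprintf("read_tissue: %s: JSON parse error at or before byte offset %d (%s)",
                   path, file.size(path), conditionMessage(e)), call. = FALSE)
    })
  known_top <- c("parameters", "vertices", "bonds", "cells", "metadata")
  check_fields(names(doc), known_top, "document", path, strict)
  pr <- doc$parameters %||% list()
  check_fields(names(pr), c("K", "A0", "Gamma_bar", "Lambda0_bar"),
               "parameters", path, strict)
  params <- model_parameters(K = pr$K %||% 1, A0 = pr$A0 %||% 1,
                             Gamma_bar = pr$Gamma_bar %||% 0.04,
                             Lambda0_bar = pr$Lambda0_bar %||% 0.12)
  V <- do.call(rbind, lapply(doc$vertices, function(v) {
    if (length(v) != 2) stop("read_tissue: ", path, ": vertex is not a 2D point")
    as.numeric(v)
  }))
  bonds <- matrix(0L, length(doc$bonds), 2)
  tension <- numeric(length(doc$bonds))
  ablated <- logical(length(doc$bonds))
  for (b in seq_along(doc$bonds)) {
    bd <- doc$bonds[[b]]
    check_fields(names(bd), c("v", "tension_bar", "ablated"),
                 sprintf("bonds[%d]", b), path, strict)
    if (length(bd$v) != 2) stop("read_tissue: ", path, ": bond endpoint pair malformed")
    bonds[b, ] <- as.integer(unlist(bd$v)) + 1L
    tension[b] <- bd$tension_bar %||% params$Lambda0_bar
    ablated[b] <- isTRUE(bd$ablated)
  }
  nc <- length(doc$cells)
  cells <- vector("list", nc)
  prefa <- numeric(nc); clone <- logical(nc); compart <- character(nc)
  for (cc in seq_len(nc)) {
    cl <- doc$cells[[cc]]
    check_fields(names(cl), c("vertices", "preferred_area", "clone", "compartment"),
                 sprintf("cells[%d]", cc), path, strict)
    cells[[cc]] <- as.integer(unlist(cl$vertices)) + 1L
    prefa[cc] <- cl$preferred_area %||% 1
    clone[cc] <- isTRUE(cl$clone)
    compart[cc] <- if (is.null(cl$compartment)) NA_character_ else cl$compartment
  }
  md <- doc$metadata %||% list(generation = 0, seed = NA_integer_, step = 0L)
  net <- tissue_network(V, bonds, tension, ablated, cells,
                        cell_prefarea = prefa, cell_clone = clone,
                        cell_compartment = compart,
                        params = params, metadata = md)
  if (validate) validate_tissue(net)
  net
}

check_fields <- function(found, known, where, path, strict) {
  unknown <- setdiff(found, known)
  if (strict && length(unknown) > 0)
    stop(sprintf("read_tissue: %s: unknown field(s) %s in %s",
                 path, paste0("'", unknown, "'", collapse = ", "), where),
         call. = FALSE)
  invisible(TRUE)
}

#' Write a run manifest
#'
#' Records the fully resolved configuration, package version and seed of a
#' run, so any output table can be regenerated from the manifest alone.
#'
#' @param config Named list of resolved configuration values.
#' @param path Output JSON path.
#' @return Invisibly, `path`.
#' @export
write_manifest <- function(config, path) {
  doc <- list(package = "epiclone",
              version = as.character(utils::packageVersion("epiclone")),
              config = config)
  writeLines(jsonlite::toJSON(doc, auto_unbox = TRUE, digits = NA, null = "null",
                              pretty = TRUE), path)
  invisible(path)
}

#' Write a roughness curve as CSV
#'
#' Columns: `statistic_kind`, `L_over_lbar`, `value_over_lbar`, `n_segments`,
#' `source_id`.
#'
#' @param curve A `roughness_curve` (from [boundary_roughness()] or
#'   [clonal_roughness()]).
#' @param path Output CSV path.
#' @param source_id Identifier of the source network.
#' @return Invisibly, `path`.
#' @export
write_roughness_csv <- function(curve, path, source_id = "") {
  df <- data.frame(statistic_kind = attr(curve, "statistic_kind"),
                   L_over_lbar = curve$L,
                   value_over_lbar = curve$value,
                   n_segments = curve$n_segments,
                   source_id = source_id)
  utils::write.csv(df, path, row.names = FALSE)
  invisible(path)
}
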