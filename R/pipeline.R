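# End-to-end orchestration: label stack (real or phantom) in, tidy CSV
# report bundle out.

#' Mean +/- SD summary row
#'
#' Summarises repeated measurements the way morphometric results are
#' reported: mean and sample standard deviation (n-1 denominator), with a
#' formatted "mean units ± SD" string. With a single sample the SD is
#' reported as 0 and flagged undefined.
#'
#' @param samples Numeric vector (n >= 1 unless `allow_empty`).
#' @param units Unit string.
#' @param quantity Quantity name recorded in the row.
#' @param digits Significant digits used in the formatted string.
#' @param allow_empty Return an empty row instead of erroring on zero
#'   samples (used by reporting code on optional quantities).
#' @return One-row tibble: `quantity`, `n`, `mean`, `sd`, `sd_defined`,
#'   `units`, `formatted`.
#' @examples
#' summarise_samples(c(1, 2, 3), "um", "example")   # mean 2, sd 1
#' @export
summarise_samples <- function(samples, units, quantity = "quantity",
                              digits = 3, allow_empty = FALSE) {
  samples <- as.numeric(samples)
  if (length(samples) == 0L) {
    if (!allow_empty) stop("cannot summarise an empty sample list",
                           call. = FALSE)
    return(tibble::tibble(quantity = quantity, n = 0L, mean = NA_real_,
                          sd = NA_real_, sd_defined = FALSE, units = units,
                          formatted = NA_character_))
  }
  m <- mean(samples)
  s <- if (length(samples) > 1L) stats::sd(samples) else 0
  tibble::tibble(
    quantity = quantity, n = length(samples), mean = m, sd = s,
    sd_defined = length(samples) > 1L, units = units,
    formatted = sprintf("%s %s ± %s SD", format(signif(m, digits)), units,
                        format(signif(s, digits))))
}

#' Pipeline run configuration
#'
#' Exactly one input source must be given: either a label stack on disk
#' (`stack` + `table_path`) or a [phantom_spec] to generate.
#'
#' @param stack Path to a multi-page TIFF label stack, or `NULL`.
#' @param table_path Path to the JSON label table (required with
#'   `stack`).
#' @param phantom A [phantom_spec], or a path to a YAML file whose fields
#'   mirror [phantom_spec] arguments, or `NULL`.
#' @param spacing A [voxel_spacing]; may be `NULL` when the label-table
#'   JSON carries `spacing_nm` or when using a phantom.
#' @param scheme A [sampling_scheme] for the geometry stage.
#' @param interface_mode `"corrected"` or `"fidelity"` for the contact
#'   stage.
#' @param area_method Surface-area estimator tag (currently
#'   `"voxel_face"`).
#' @param mito_connectivity 26, 18 or 6.
#' @param out_dir Output directory (created if absent).
#' @param seed Integer seed for every stochastic stage.
#' @return A list of class `run_config`.
#' @export
run_config <- function(stack = NULL, table_path = NULL, phantom = NULL,
                       spacing = NULL, scheme = sampling_scheme(),
                       interface_mode = c("corrected", "fidelity"),
                       area_method = "voxel_face", mito_connectivity = 26,
                       out_dir = tempfile("rpemorph_run_"), seed = 1L) {
  interface_mode <- match.arg(interface_mode)
  if (is.null(stack) == is.null(phantom)) {
    stop("supply exactly one of `stack` or `phantom`", call. = FALSE)
  }
  if (!is.null(stack) && is.null(table_path)) {
    stop("`table_path` is required with `stack`", call. = FALSE)
  }
  if (is.character(phantom)) {
    if (!requireNamespace("yaml", quietly = TRUE)) {
      stop("reading a YAML phantom spec requires the yaml package",
           call. = FALSE)
    }
    args <- yaml::read_yaml(phantom)
    if (!is.null(args$spacing)) {
      args$spacing <- do.call(voxel_spacing, as.list(args$spacing))
    }
    phantom <- do.call(phantom_spec, args)
  }
  structure(list(stack = stack, table_path = table_path, phantom = phantom,
                 spacing = spacing, scheme = scheme,
                 interface_mode = interface_mode,
                 area_method = area_method,
                 mito_connectivity = mito_connectivity,
                 out_dir = out_dir, seed = as.integer(seed)),
            class = "run_config")
}

#' Run the full morphometry pipeline
#'
#' Phantom or real label stack in; Table-1/Table-2/contact-map shaped CSV
#' reports and mean +/- SD summaries out. Stages: input, morphometry
#' (per-compartment volumes/areas and per-cell summaries), mitochondria,
#' cell-cell interfaces, photoreceptor contacts, geometry (microvilli,
#' heights, Bruch's membrane), summary. Every CSV carries the provenance
#' columns `mode`, `area_method` and `connectivity`; `run.json` records
#' the configuration, seed, package version and per-stage wall times.
#' The run is deterministic for a fixed config and seed (byte-identical
#' CSVs). A failing stage aborts with the stage name and removes partial
#' outputs.
#'
#' @param config A [run_config].
#' @return Invisibly, a list with the output `paths` and the result
#'   tibbles (`morpho`, `cells`, `mito`, `interfaces`, `contacts`,
#'   `geometry`, `summary`, and `truth` for phantom runs).
#' @export
run_all <- function(config) {
  stopifnot(inherits(config, "run_config"))
  dir.create(config$out_dir, showWarnings = FALSE, recursive = TRUE)
  paths <- file.path(config$out_dir,
                     c(morpho = "morpho.csv", mito = "mito.csv",
                       interfaces = "interfaces.csv",
                       contacts = "contacts.csv",
                       geometry = "geometry.csv", summary = "summary.csv",
                       run = "run.json"))
  names(paths) <- c("morpho", "mito", "interfaces", "contacts", "geometry",
                    "summary", "run")
  timings <- list()
  current_stage <- "input"
  res <- tryCatch({
    tic <- function() proc.time()[["elapsed"]]
    stage <- function(name, expr) {
      current_stage <<- name
      t0 <- tic()
      out <- force(expr)
      timings[[name]] <<- round(tic() - t0, 3)
      out
    }
    inp <- stage("input", {
      if (!is.null(config$phantom)) {
        ph <- generate_phantom(config$phantom)
        list(vol = ph$volume, truth = ph$truth)
      } else {
        list(vol = read_label_stack(config$stack, config$spacing,
                                    config$table_path), truth = NULL)
      }
    })
    vol <- inp$vol
    cells <- cell_ids(vol)
    prov <- function(df) {
      df$mode <- config$interface_mode
      df$area_method <- config$area_method
      df$connectivity <- config$mito_connectivity
      df
    }

    morpho <- stage("morphometry", morphometry_table(vol))
    contacts <- stage("contacts", suppressWarnings(os_support_table(vol)))
    cells_tab <- stage("cell_summaries", dplyr::bind_rows(lapply(
      cells, function(cid) {
        suppressWarnings(cell_summary(vol, cid, os_assignment = contacts,
                                      morpho = morpho))
      })))
    mito <- stage("mitochondria", dplyr::bind_rows(lapply(
      cells, function(cid) {
        generics::glance(mitochondria_stats(vol, cid,
                                            config$mito_connectivity))
      })))
    interfaces <- stage("interfaces", {
      if (length(cells) >= 2L) {
        cell_contact_areas(vol, mode = config$interface_mode)
      } else {
        tibble::tibble(cell_a = character(), cell_b = character(),
                       label_a = character(), label_b = character(),
                       mode = character(), n_slices = integer(),
                       total_area_um2 = numeric(),
                       mean_slice_area_um2 = numeric(),
                       face_area_um2 = numeric())
      }
    })
    geometry <- stage("geometry", {
      sch <- config$scheme
      rows <- list()
      pooled <- list(mv_len = numeric(0), mv_ang = numeric(0),
                     body = numeric(0), combined = numeric(0))
      for (cid in cells) {
        has_mv <- length(labels_for(vol$table, cell = cid,
                                    compartment = "microvilli")) > 0
        mg <- if (has_mv) microvillus_geometry(vol, cid, sch) else NULL
        ht <- rpe_height(vol, cid, sch,
                         microvilli_length = if (is.null(mg)) 0 else
                           mg$length$mean)
        if (!is.null(mg)) {
          rows[[length(rows) + 1L]] <- dplyr::mutate(dplyr::bind_rows(
            generics::glance(mg$length), generics::glance(mg$angle)),
            cell_id = cid)
          pooled$mv_len <- c(pooled$mv_len, mg$length$samples)
          pooled$mv_ang <- c(pooled$mv_ang, mg$angle$samples)
        }
        rows[[length(rows) + 1L]] <- dplyr::mutate(
          generics::glance(ht$body_height), cell_id = cid)
        rows[[length(rows) + 1L]] <- tibble::tibble(
          quantity = "combined_height", n = ht$body_height$n,
          mean = ht$combined_height_um, sd = NA_real_, units = "um",
          cell_id = cid)
        pooled$body <- c(pooled$body, ht$body_height$samples)
        pooled$combined <- c(pooled$combined, ht$combined_height_um)
      }
      brm <- tryCatch(brm_thickness(vol, sch), error = function(e) NULL)
      if (!is.null(brm)) {
        rows[[length(rows) + 1L]] <- dplyr::mutate(generics::glance(brm),
                                                   cell_id = "all")
      }
      list(table = dplyr::bind_rows(rows), pooled = pooled, brm = brm)
    })
    summary_tab <- stage("summary", {
      p <- geometry$pooled
      rows <- list()
      add <- function(x, units, q) {
        if (length(x) > 0) {
          rows[[length(rows) + 1L]] <<- summarise_samples(x, units, q)
        }
      }
      add(p$mv_len, "um", "microvillus_length")
      add(p$mv_ang, "deg", "microvillus_angle")
      add(p$body, "um", "rpe_body_height")
      add(p$combined, "um", "rpe_combined_height")
      if (!is.null(geometry$brm)) {
        add(geometry$brm$samples, "nm", "brm_thickness")
      }
      add(interfaces$total_area_um2, "um^2", "cell_contact_area_slicewise")
      add(interfaces$face_area_um2, "um^2", "cell_contact_area_voxelface")
      add(cells_tab$cytoplasm_volume_um3, "um^3", "cytoplasm_volume")
      dplyr::bind_rows(rows)
    })

    # Table-1-shaped long view
    morpho_long <- dplyr::bind_rows(
      dplyr::transmute(morpho, cell_id = .data$cell_id,
                       quantity = paste0(.data$compartment, "_volume"),
                       value = .data$volume_um3, units = "um^3"),
      dplyr::transmute(morpho, cell_id = .data$cell_id,
                       quantity = paste0(.data$compartment,
                                         "_surface_area"),
                       value = .data$surface_area_um2, units = "um^2"),
      dplyr::transmute(cells_tab, cell_id = .data$cell_id,
                       quantity = "cytoplasm_volume",
                       value = .data$cytoplasm_volume_um3, units = "um^3"),
      dplyr::transmute(cells_tab, cell_id = .data$cell_id,
                       quantity = "nucleus_excluded_volume",
                       value = .data$nucleus_excluded_volume_um3,
                       units = "um^3"),
      dplyr::transmute(cells_tab, cell_id = .data$cell_id,
                       quantity = "photoreceptors_supported",
                       value = as.numeric(.data$photoreceptors_supported),
                       units = "count"),
      dplyr::transmute(cells_tab, cell_id = .data$cell_id,
                       quantity = "photoreceptor_density",
                       value = .data$photoreceptor_density_2sf,
                       units = "per um^3"),
      dplyr::transmute(cells_tab, cell_id = .data$cell_id,
                       quantity = "microvilli_os_contact_area",
                       value = .data$microvilli_contact_area_um2,
                       units = "um^2"))
    morpho_long <- dplyr::arrange(morpho_long, .data$cell_id,
                                  .data$quantity)

    stage("write", {
      readr::write_csv(prov(morpho_long), paths[["morpho"]])
      readr::write_csv(prov(mito), paths[["mito"]])
      readr::write_csv(prov(interfaces), paths[["interfaces"]])
      readr::write_csv(prov(contacts), paths[["contacts"]])
      readr::write_csv(prov(geometry$table), paths[["geometry"]])
      readr::write_csv(prov(summary_tab), paths[["summary"]])
    })
    run_meta <- list(
      package = "rpemorph",
      version = as.character(utils::packageVersion("rpemorph")),
      seed = config$seed,
      interface_mode = config$interface_mode,
      area_method = config$area_method,
      mito_connectivity = config$mito_connectivity,
      scheme = unclass(config$scheme),
      input = if (is.null(config$phantom)) {
        list(kind = "stack", stack = config$stack,
             table = config$table_path)
      } else list(kind = "phantom", seed = config$phantom$seed),
      timings_s = timings,
      outputs = basename(unname(paths[names(paths) != "run"])))
    jsonlite::write_json(run_meta, paths[["run"]], auto_unbox = TRUE,
                         digits = NA)
    list(paths = paths, morpho = morpho_long, compartments = morpho,
         cells = cells_tab, mito = mito, interfaces = interfaces,
         contacts = contacts, geometry = geometry$table,
         summary = summary_tab, truth = inp$truth)
  }, error = function(e) {
    unlink(paths[file.exists(paths)])
    stop("pipeline stage '", current_stage, "' failed: ",
         conditionMessage(e), call. = FALSE)
  })
  invisible(res)
}
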