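#' Write a sweep set as delimited text plus JSON sidecar
#'
#' One block per sweep, each introduced by a `# sweep` header line, with
#' columns `time_ms`, `voltage_mV`, `current_uA`, `fluorescence_au`. Protocol
#' and metadata (including any generator ground truth and seed) go to a
#' `.json` sidecar next to the data file.
#'
#' @param sweeps A `sweep_set`.
#' @param path Output file path (sidecar gets `.json` appended).
#' @return Invisibly, `path`.
#' @export
write_sweep_set <- function(sweeps, path) {
  stopifnot(inherits(sweeps, "sweep_set"))
  con <- file(path, "w")
  on.exit(close(con))
  for (j in seq_along(sweeps$test_potentials)) {
    v <- sweeps$test_potentials[j]
    writeLines(sprintf("# sweep %d test_potential_mV %.6g", j, v), con)
    writeLines("time_ms\tvoltage_mV\tcurrent_uA\tfluorescence_au", con)
    df <- data.frame(time_ms = sweeps$time_ms,
                     voltage_mV = command_voltage(sweeps$protocol, v),
                     current_uA = sweeps$current[, j],
                     fluorescence_au = sweeps$fluorescence[, j])
    write.table(format(df, digits = 9, trim = TRUE, scientific = FALSE),
                con, sep = "\t", quote = FALSE,
                row.names = FALSE, col.names = FALSE)
  }
  gt <- sweeps$ground_truth
  meta <- list(cell_id = sweeps$cell_id,
               treatment_label = sweeps$treatment_label,
               day_id = sweeps$day_id, seed = sweeps$seed,
               protocol = unclass(sweeps$protocol),
               ground_truth = if (!is.null(gt))
                 Filter(Negate(is.function), unclass(gt)))
  jsonlite::write_json(meta, paste0(path, ".json"), auto_unbox = TRUE,
                       digits = NA, null = "null")
  invisible(path)
}

#' Read a sweep set written by [write_sweep_set()]
#'
#' @param path Data file path (expects the `.json` sidecar next to it).
#' @return A `sweep_set` (ground-truth time-constant functions are not
#'   restored; scalar ground-truth fields are kept as a plain list in
#'   `$ground_truth_meta`).
#' @export
read_sweep_set <- function(path) {
  meta <- jsonlite::read_json(paste0(path, ".json"), simplifyVector = TRUE)
  proto <- do.call(voltage_protocol, meta$protocol)
  lines <- readLines(path)
  starts <- grep("^# sweep ", lines)
  stopifnot(length(starts) >= 1)
  ends <- c(starts[-1] - 1, length(lines))
  vs <- numeric(length(starts))
  cur <- flu <- matrix(NA_real_, protocol_n_samples(proto), length(starts))
  for (b in seq_along(starts)) {
    hdr <- strsplit(lines[starts[b]], " ")[[1]]
    vs[b] <- as.numeric(hdr[length(hdr)])
    block <- read.table(text = lines[(starts[b] + 2):ends[b]], sep = "\t")
    cur[, b] <- block[[3]]
    flu[, b] <- block[[4]]
  }
  ss <- sweep_set(cell_id = meta$cell_id,
                  treatment_label = meta$treatment_label,
                  day_id = meta$day_id, protocol = proto,
                  test_potentials = vs, current = cur, fluorescence = flu)
  ss$ground_truth_meta <- meta$ground_truth
  ss$seed <- meta$seed
  ss
}

# intensities are stored as 16-bit TIFF scaled by this full-scale count
.tiff_full_scale <- 65535

#' Write a two-channel ratio image set
#'
#' The two excitation channels go to a two-page 16-bit TIFF (page 1 = blue
#' channel, page 2 = red channel; counts scaled by 1/65535) and the seed
#' points to a three-column text file (`row`, `col`, `kind`) with 0-based
#' pixel coordinates.
#'
#' @param image_set A `ratio_image_set`.
#' @param tiff_path,seeds_path Output paths.
#' @return Invisibly, `tiff_path`.
#' @export
write_ratio_image_set <- function(image_set, tiff_path, seeds_path) {
  quantize <- function(x)
    pmax(pmin(round(x), .tiff_full_scale), 0) / .tiff_full_scale
  pages <- list(quantize(image_set$channel_blue),
                quantize(image_set$channel_red))
  tiff::writeTIFF(pages, tiff_path, bits.per.sample = 16)
  seeds <- image_set$seeds
  seeds$row <- seeds$row - 1L
  seeds$col <- seeds$col - 1L
  write.table(seeds, seeds_path, sep = "\t", quote = FALSE,
              row.names = FALSE)
  invisible(tiff_path)
}

#' Read a two-channel ratio image set
#'
#' @param tiff_path Two-page TIFF (page 1 = blue, page 2 = red).
#' @param seeds_path Seed text file with 0-based `row`, `col`, `kind`.
#' @return A `ratio_image_set` (without ground-truth masks).
#' @export
read_ratio_image_set <- function(tiff_path, seeds_path) {
  pages <- tiff::readTIFF(tiff_path, all = TRUE)
  stopifnot(length(pages) == 2)
  seeds <- read.table(seeds_path, header = TRUE,
                      colClasses = c("integer", "integer", "character"))
  seeds$row <- seeds$row + 1L
  seeds$col <- seeds$col + 1L
  structure(list(channel_blue = pages[[1]] * .tiff_full_scale,
                 channel_red = pages[[2]] * .tiff_full_scale,
                 seeds = seeds),
            class = "ratio_image_set")
}

#' Write a processed per-cell summary table
#'
#' Per-sweep summary points (test potential, leak-corrected peak current,
#' steady-state dF/F) as tab-delimited text with a JSON sidecar of the
#' processing parameters.
#'
#' @param proc A `processed_sweep_set`.
#' @param path Output file path.
#' @return Invisibly, `path`.
#' @export
write_processed_table <- function(proc, path) {
  df <- data.frame(test_potential_mV = proc$parent$test_potentials,
                   peak_current_uA = proc$peak_current,
                   steady_state_dff_pct = proc$steady_state_dff)
  write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  jsonlite::write_json(c(list(cell_id = proc$parent$cell_id,
                              leak = proc$leak), proc$params),
                       paste0(path, ".json"), auto_unbox = TRUE, digits = NA)
  invisible(path)
}
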