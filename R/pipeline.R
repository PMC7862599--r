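#' Write an ImageField as multipage TIFF plus JSON sidecar
#'
#' Intensities are stored as 16-bit TIFF pages (one page per channel),
#' scaled by 1/65535; the sidecar records channel names, pixel size and an
#' optional seed so the field round-trips exactly.
#'
#' @param field an \linkS4class{ImageField}.
#' @param prefix output path prefix; writes \code{<prefix>.tif} and
#'   \code{<prefix>.json}.
#' @param seed optional seed recorded in the sidecar.
#' @return invisibly, the TIFF path.
#' @export
writeImageField <- function(field, prefix, seed = NULL) {
  pages <- lapply(field@channels, function(m) {
    m <- round(pmax(pmin(m, 65535), 0))
    m / 65535
  })
  tif <- paste0(prefix, ".tif")
  tiff::writeTIFF(unname(pages), tif, bits.per.sample = 16L)
  meta <- list(channels = channelNames(field), pixel_size = pixelSize(field),
               field_id = field@fieldId)
  if (!is.null(seed)) meta$seed <- seed
  jsonlite::write_json(meta, paste0(prefix, ".json"), auto_unbox = TRUE,
                       digits = NA)
  invisible(tif)
}

#' Read an ImageField written by \code{\link{writeImageField}}
#'
#' @param prefix path prefix of the \code{.tif}/\code{.json} pair.
#' @return an \linkS4class{ImageField}.
#' @export
readImageField <- function(prefix) {
  tif <- paste0(prefix, ".tif"); js <- paste0(prefix, ".json")
  if (!file.exists(tif) || !file.exists(js))
    stop("missing image or sidecar for prefix '", prefix, "'")
  meta <- jsonlite::read_json(js, simplifyVector = TRUE)
  pages <- tiff::readTIFF(tif, all = TRUE)
  if (length(pages) != length(meta$channels))
    stop("channel count mismatch between TIFF and sidecar for '", prefix, "'")
  channels <- lapply(pages, function(p) round(p * 65535))
  names(channels) <- meta$channels
  ImageField(channels, pixelSize = meta$pixel_size,
             fieldId = if (!is.null(meta$field_id)) meta$field_id else prefix)
}

# deterministic polynomial hash of a config (order-stable JSON serialization)
.configHash <- function(config) {
  s <- jsonlite::toJSON(config, auto_unbox = TRUE, digits = 12)
  bytes <- as.integer(charToRaw(as.character(s)))
  h <- 0
  for (b in bytes) h <- (h * 31 + b) %% 2147483647
  sprintf("%08x", h)
}

#' Score one immunofluorescence field into per-nucleus records
#'
#' Segments nuclei, detects foci, computes diffuse metrics, optionally gates
#' regions, and classifies every nucleus.
#'
#' @param field an \linkS4class{ImageField}.
#' @param case_id case identifier.
#' @param seg_cfg,foci_cfg,cls_cfg,region_cfg stage parameter objects.
#' @param assign_regions gate nuclei with FDC/BCL2 channels when present.
#' @return list: \code{records} (per-nucleus data.frame), \code{foci},
#'   \code{masks}.
#' @export
scoreIfField <- function(field, case_id = "case",
                         seg_cfg = segmentationParams(),
                         foci_cfg = fociParams(),
                         cls_cfg = classifierParams(),
                         region_cfg = regionParams(),
                         assign_regions = FALSE) {
  masks <- segmentNuclei(field, seg_cfg)
  foci <- detectFoci(field, masks, foci_cfg)
  dm <- diffuseMetrics(field, masks, channel = foci_cfg$channel)
  region <- if (assign_regions) assignRegion(field, masks, region_cfg) else NULL
  records <- if (nrow(masks$nuclei))
    buildNucleusRecords(masks, foci, dm, case_id, cls_cfg, region)
  else NULL
  list(records = records, foci = foci, masks = masks)
}

#' Run the immunofluorescence scoring pipeline over a directory of fields
#'
#' Reads every \code{.tif}/\code{.json} field pair under
#' \code{config$input_dir} (file names \code{<case>_<field>}; the case id is
#' the part before the last underscore), scores each field, summarizes each
#' case, and writes \code{nuclei.csv}, \code{foci.csv} and \code{cases.csv}
#' to \code{config$output_dir} together with a JSON run report.
#'
#' @param config list (or path to a JSON file) with \code{input_dir},
#'   \code{output_dir}, and optional stage parameter overrides
#'   (\code{min_area_um2}, \code{rel_threshold}, \code{min_snr},
#'   \code{diffuse_min_coverage}, \code{diffuse_min_heterogeneity},
#'   \code{assign_regions}).
#' @return list of class \code{runReport}: \code{cases} (per-case summary
#'   data.frame), \code{n_fields}, \code{n_nuclei}, \code{config_hash},
#'   \code{output_dir}, \code{log}.
#' @export
runIfPipeline <- function(config) {
  if (is.character(config)) config <- jsonlite::read_json(config, simplifyVector = TRUE)
  stopifnot(!is.null(config$input_dir), !is.null(config$output_dir))
  tifs <- sort(list.files(config$input_dir, pattern = "\\.tif$",
                          full.names = TRUE))
  if (length(tifs) == 0)
    stop("no .tif fields found in '", config$input_dir, "'")
  prefixes <- sub("\\.tif$", "", tifs)
  seg_cfg <- segmentationParams(
    min_area_um2 = config$min_area_um2 %||% 15)
  foci_cfg <- fociParams(
    rel_threshold = config$rel_threshold %||% 0.2,
    min_snr = config$min_snr %||% 6)
  cls_cfg <- classifierParams(
    diffuse_min_coverage = config$diffuse_min_coverage %||% 0.4,
    diffuse_min_heterogeneity = config$diffuse_min_heterogeneity %||% 0.3)
  log <- character(0)
  all_rec <- list(); all_foci <- list()
  for (p in prefixes) {
    field <- readImageField(p)
    case_id <- sub("_[^_]*$", "", basename(p))
    sc <- scoreIfField(field, case_id, seg_cfg, foci_cfg, cls_cfg,
                       assign_regions = isTRUE(config$assign_regions))
    log <- c(log, sprintf("%s: %d nuclei, %d foci", basename(p),
                          nrow(sc$masks$nuclei), nrow(sc$foci)))
    if (!is.null(sc$records)) {
      sc$records$field <- basename(p)
      sc$foci$field <- if (nrow(sc$foci)) basename(p) else character(0)
      all_rec[[p]] <- sc$records
      all_foci[[p]] <- sc$foci
    }
  }
  records <- do.call(rbind, all_rec)
  if (is.null(records) || nrow(records) == 0)
    stop("pipeline found no nuclei in any field")
  foci <- do.call(rbind, all_foci)
  cases <- do.call(rbind, lapply(split(records, records$case_id),
                                 summarizeCase))
  rownames(cases) <- NULL
  dir.create(config$output_dir, showWarnings = FALSE, recursive = TRUE)
  utils::write.csv(records, file.path(config$output_dir, "nuclei.csv"),
                   row.names = FALSE)
  utils::write.csv(foci, file.path(config$output_dir, "foci.csv"),
                   row.names = FALSE)
  utils::write.csv(cases, file.path(config$output_dir, "cases.csv"),
                   row.names = FALSE)
  report <- structure(list(cases = cases, n_fields = length(prefixes),
                           n_nuclei = nrow(records),
                           config_hash = .configHash(config),
                           output_dir = config$output_dir, log = log),
                      class = "runReport")
  jsonlite::write_json(
    list(n_fields = report$n_fields, n_nuclei = report$n_nuclei,
         config_hash = report$config_hash, log = log),
    file.path(config$output_dir, "report.json"), auto_unbox = TRUE)
  report
}

#' Run the FISH genotyping pipeline over a directory of fields
#'
#' Reads every field pair under \code{config$input_dir} (all fields belong
#' to one slide unless file names carry distinct case prefixes), detects
#' green/orange signals, calls per-nucleus genotypes and summarizes each
#' slide with the informativeness rules. Writes \code{fish_nuclei.csv} and
#' \code{fish_cases.csv}.
#'
#' @param config list (or JSON path) with \code{input_dir},
#'   \code{output_dir}, optional \code{max_pair_distance},
#'   \code{min_nuclei}, \code{case_fraction_threshold}.
#' @return list of class \code{runReport} with \code{cases} holding the
#'   per-slide \code{\link{summarizeFishCase}} rows.
#' @export
runFishPipeline <- function(config) {
  if (is.character(config)) config <- jsonlite::read_json(config, simplifyVector = TRUE)
  stopifnot(!is.null(config$input_dir), !is.null(config$output_dir))
  tifs <- sort(list.files(config$input_dir, pattern = "\\.tif$",
                          full.names = TRUE))
  if (length(tifs) == 0)
    stop("no .tif fields found in '", config$input_dir, "'")
  cfg <- fishParams(
    max_pair_distance = config$max_pair_distance %||% 0.6,
    min_nuclei = config$min_nuclei %||% 150,
    case_fraction_threshold = config$case_fraction_threshold %||% 10)
  log <- character(0); all_calls <- list()
  for (p in sub("\\.tif$", "", tifs)) {
    field <- readImageField(p)
    case_id <- sub("_[^_]*$", "", basename(p))
    masks <- segmentNuclei(field)
    sig <- detectFishSignals(field, masks, cfg)
    calls <- callFishNuclei(sig, nucleus_ids = masks$nuclei$nucleus_id,
                            cfg = cfg)
    log <- c(log, sprintf("%s: %d nuclei, %d signals", basename(p),
                          nrow(masks$nuclei), nrow(sig)))
    if (!is.null(calls)) {
      calls$case_id <- case_id; calls$field <- basename(p)
      all_calls[[p]] <- calls
    }
  }
  calls <- do.call(rbind, all_calls)
  if (is.null(calls) || nrow(calls) == 0)
    stop("pipeline found no nuclei in any field")
  cases <- do.call(rbind, lapply(split(calls, calls$case_id), function(cc)
    summarizeFishCase(cc, cfg, case_id = cc$case_id[1])))
  rownames(cases) <- NULL
  dir.create(config$output_dir, showWarnings = FALSE, recursive = TRUE)
  utils::write.csv(calls, file.path(config$output_dir, "fish_nuclei.csv"),
                   row.names = FALSE)
  utils::write.csv(cases, file.path(config$output_dir, "fish_cases.csv"),
                   row.names = FALSE)
  structure(list(cases = cases, n_fields = length(tifs),
                 n_nuclei = nrow(calls), config_hash = .configHash(config),
                 output_dir = config$output_dir, log = log),
            class = "runReport")
}

#' @export
print.runReport <- function(x, ...) {
  cat("Pipeline run:", x$n_fields, "fields,", x$n_nuclei,
      "nuclei; config", x$config_hash, "\n")
  print(x$cases)
  invisible(x)
}

`%||%` <- function(a, b) if (is.null(a)) b else a
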