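#' Tomogram stack container
#'
#' A `tomogram_stack` wraps a 3D array of gray values together with its voxel
#' spacing in nm. Arrays are indexed `[y, x, z]` (row, column, slice); the
#' spacing vector is named `(x, y, z)`. Gray values are stored as read — no
#' dtype rescaling happens at load time.
#'
#' @param voxels numeric array; a 2D matrix is promoted to a single-slice 3D
#'   array.
#' @param spacing numeric length-3 (nm/voxel), named or in (x, y, z) order;
#'   all entries must be positive.
#' @param id tomogram identifier string.
#' @return An object of class `tomogram_stack` with fields `voxels`,
#'   `spacing`, `id`.
#' @export
tomogram_stack <- function(voxels, spacing = c(x = 1, y = 1, z = 1),
                           id = "stack") {
  if (is.matrix(voxels)) voxels <- array(voxels, dim = c(dim(voxels), 1L))
  if (length(dim(voxels)) != 3L)
    stop("stack must be a 3D array (or a 2D matrix)", call. = FALSE)
  if (dim(voxels)[3] < 1L) stop("stack needs at least one slice", call. = FALSE)
  spacing <- as.numeric(spacing)
  if (length(spacing) != 3L || any(!is.finite(spacing)) || any(spacing <= 0))
    stop("spacing must be three positive finite values (x, y, z)", call. = FALSE)
  if (any(!is.finite(voxels)))
    stop("stack contains non-finite gray values", call. = FALSE)
  structure(list(voxels = voxels, spacing = c(x = spacing[1], y = spacing[2],
                                              z = spacing[3]),
                 id = as.character(id)),
            class = "tomogram_stack")
}

#' @export
print.tomogram_stack <- function(x, ...) {
  d <- dim(x$voxels)
  cat(sprintf("tomogram_stack '%s': %d x %d x %d voxels, spacing (%g, %g, %g) nm\n",
              x$id, d[2], d[1], d[3], x$spacing[1], x$spacing[2], x$spacing[3]))
  invisible(x)
}

#' @export
dim.tomogram_stack <- function(x) dim(x$voxels)

guess_format <- function(path) {
  ext <- tolower(tools::file_ext(path))
  if (ext %in% c("tif", "tiff")) return("tiff")
  if (ext %in% c("mrc", "rec", "st", "map")) return("mrc")
  stop("cannot infer stack format from extension: ", path, call. = FALSE)
}

#' Read a tomogram stack from TIFF or MRC
#'
#' Multi-page TIFF and MRC (MRC2014; modes 0, 1, 2) are supported. For MRC,
#' the voxel size recorded in the header (`cella/mx` etc., converted from
#' angstrom to nm) is used when present and no `spacing` override is given.
#'
#' @param path file path (`.tif`/`.tiff` or `.mrc`/`.rec`).
#' @param spacing optional (x, y, z) nm/voxel override; required for TIFF if
#'   a spacing other than 1 nm is meant.
#' @param id identifier; defaults to the file name.
#' @return [tomogram_stack()]
#' @export
read_stack <- function(path, spacing = NULL, id = NULL) {
  if (!file.exists(path)) stop("no such file: ", path, call. = FALSE)
  if (is.null(id)) id <- tools::file_path_sans_ext(basename(path))
  fmt <- guess_format(path)
  if (fmt == "tiff") {
    pages <- tryCatch(tiff::readTIFF(path, all = TRUE, as.is = TRUE),
                      error = function(e)
                        stop("unreadable TIFF: ", conditionMessage(e),
                             call. = FALSE))
    if (!is.list(pages)) pages <- list(pages)
    if (any(vapply(pages, function(p) length(dim(p)) != 2L, logical(1))))
      stop("TIFF pages must be single-channel 2D images", call. = FALSE)
    vox <- array(unlist(pages), dim = c(dim(pages[[1]]), length(pages)))
    if (is.null(spacing)) spacing <- c(1, 1, 1)
    tomogram_stack(vox, spacing, id)
  } else {
    mrc <- read_mrc(path)
    if (is.null(spacing)) spacing <- mrc$spacing
    tomogram_stack(mrc$voxels, spacing, id)
  }
}

#' Write a tomogram stack to TIFF or MRC
#'
#' TIFF output is written with the given bit depth (gray values are assumed
#' to lie in `[0, 2^bits - 1]`); MRC output uses mode 2 (float32) unless the
#' data are integral and fit mode 1 (int16).
#'
#' @param stack [tomogram_stack()]
#' @param path destination; format chosen by extension.
#' @param bits TIFF bits per sample (8 or 16).
#' @return `path`, invisibly.
#' @export
write_stack <- function(stack, path, bits = 8L) {
  stopifnot(inherits(stack, "tomogram_stack"))
  fmt <- guess_format(path)
  if (fmt == "tiff") {
    maxval <- 2^bits - 1
    v <- stack$voxels
    if (min(v) < 0 || max(v) > maxval)
      stop("gray values outside [0, ", maxval, "] cannot be written at ",
           bits, " bits", call. = FALSE)
    pages <- lapply(seq_len(dim(v)[3]), function(z) v[, , z] / maxval)
    tiff::writeTIFF(pages, path, bits.per.sample = as.integer(bits),
                    compression = "none")
  } else {
    write_mrc(stack, path)
  }
  invisible(path)
}

# ---- minimal MRC2014 reader/writer (modes 0 = int8, 1 = int16, 2 = float32;
# header cell dimensions in angstrom, so nm spacing = cella / (10 * m)) ----

read_mrc <- function(path) {
  con <- file(path, "rb")
  on.exit(close(con))
  hdr <- readBin(con, "integer", n = 10, size = 4, endian = "little")
  nx <- hdr[1]; ny <- hdr[2]; nz <- hdr[3]; mode <- hdr[4]
  mx <- hdr[8]; my <- hdr[9]; mz <- hdr[10]
  cella <- readBin(con, "numeric", n = 3, size = 4, endian = "little")
  if (any(c(nx, ny, nz) <= 0) || !(mode %in% c(0L, 1L, 2L)))
    stop("unsupported or corrupt MRC header (mode ", mode, ")", call. = FALSE)
  seek(con, 92)
  nsymbt <- readBin(con, "integer", n = 1, size = 4, endian = "little")
  seek(con, 1024 + nsymbt)
  n <- as.numeric(nx) * ny * nz
  v <- switch(as.character(mode),
    "0" = readBin(con, "integer", n = n, size = 1, signed = TRUE,
                  endian = "little"),
    "1" = readBin(con, "integer", n = n, size = 2, signed = TRUE,
                  endian = "little"),
    "2" = readBin(con, "numeric", n = n, size = 4, endian = "little"))
  if (length(v) != n) stop("truncated MRC data block", call. = FALSE)
  vox <- aperm(array(as.numeric(v), dim = c(nx, ny, nz)), c(2, 1, 3))
  spacing <- c(1, 1, 1)
  if (all(cella > 0) && all(c(mx, my, mz) > 0))
    spacing <- cella / c(mx, my, mz) / 10  # angstrom -> nm
  list(voxels = vox, spacing = spacing, mode = mode)
}

write_mrc <- function(stack, path) {
  v <- stack$voxels
  d <- dim(v)
  ny <- d[1]; nx <- d[2]; nz <- d[3]
  integral <- all(v == round(v)) && min(v) >= -32768 && max(v) <= 32767
  mode <- if (integral) 1L else 2L
  con <- file(path, "wb")
  on.exit(close(con))
  writeBin(as.integer(c(nx, ny, nz, mode, 0L, 0L, 0L, nx, ny, nz)), con,
           size = 4, endian = "little")
  cella <- c(nx * stack$spacing[1], ny * stack$spacing[2],
             nz * stack$spacing[3]) * 10  # nm -> angstrom
  writeBin(as.numeric(c(cella, 90, 90, 90)), con, size = 4, endian = "little")
  writeBin(as.integer(c(1L, 2L, 3L)), con, size = 4, endian = "little")
  writeBin(as.numeric(c(min(v), max(v), mean(v))), con, size = 4,
           endian = "little")
  writeBin(integer(2), con, size = 4, endian = "little")  # ispg, nsymbt
  writeBin(raw(100), con)                                 # extra
  writeBin(numeric(3), con, size = 4, endian = "little")  # origin
  writeChar("MAP ", con, nchars = 4, eos = NULL)
  writeBin(as.raw(c(0x44, 0x44, 0x00, 0x00)), con)        # machine stamp (LE)
  writeBin(as.numeric(stats::sd(v)), con, size = 4, endian = "little")
  writeBin(0L, con, size = 4, endian = "little")          # nlabl
  writeBin(raw(800), con)
  dat <- as.vector(aperm(v, c(2, 1, 3)))
  if (mode == 1L) writeBin(as.integer(dat), con, size = 2, endian = "little")
  else writeBin(as.numeric(dat), con, size = 4, endian = "little")
  invisible(path)
}

# ---- feature tables ----

FEATURE_COLS <- c("r", "gv", "GVSD", "distAZ")
LABEL_CODES <- c("C", "D", "N", "E")

#' Read a per-vesicle feature table (CSV)
#'
#' The expected layout has five columns: the four features and one manual
#' label column with codes `C` (clear core), `D` (dense core), `N`
#' (non-determinable) and `E` (error / excluded). A header row naming the
#' columns is used when present; otherwise `schema` fixes the column order.
#'
#' @param path CSV file.
#' @param schema column order assumed for headerless files.
#' @param id source identifier; defaults to the file name.
#' @return data.frame with columns `r`, `gv`, `GVSD`, `distAZ`, `label` and
#'   attribute `source_id`.
#' @export
read_feature_csv <- function(path,
                             schema = c("r", "gv", "GVSD", "distAZ", "label"),
                             id = NULL) {
  if (!file.exists(path)) stop("no such file: ", path, call. = FALSE)
  if (is.null(id)) id <- tools::file_path_sans_ext(basename(path))
  stopifnot(setequal(schema, c(FEATURE_COLS, "label")))
  first <- readLines(path, n = 1L)
  if (length(first) == 0L) {  # completely empty file: treat as empty table
    tab <- as.data.frame(setNames(rep(list(numeric(0)), 4), FEATURE_COLS))
    tab$label <- character(0)
    attr(tab, "source_id") <- id
    return(tab)
  }
  fields <- strsplit(first, ",", fixed = TRUE)[[1]]
  if (length(fields) != 5L)
    stop("feature CSV must have exactly 5 columns, found ", length(fields),
         " in ", path, call. = FALSE)
  featureish <- setdiff(seq_len(5L), which(schema == "label"))
  has_header <- any(is.na(suppressWarnings(as.numeric(fields[featureish])))) &&
    !all(trimws(fields) %in% LABEL_CODES)
  raw <- read.csv(path, header = has_header, stringsAsFactors = FALSE,
                  strip.white = TRUE, colClasses = "character")
  if (ncol(raw) != 5L)
    stop("feature CSV must have exactly 5 columns, found ", ncol(raw),
         call. = FALSE)
  names(raw) <- if (has_header) {
    nm <- trimws(names(raw))
    if (!setequal(nm, c(FEATURE_COLS, "label")))
      stop("unrecognized header columns: ", paste(nm, collapse = ", "),
           call. = FALSE)
    nm
  } else schema
  tab <- raw[, c(FEATURE_COLS, "label")]
  for (cn in FEATURE_COLS) {
    num <- suppressWarnings(as.numeric(tab[[cn]]))
    if (any(is.na(num) & nzchar(tab[[cn]])) || any(!nzchar(tab[[cn]])))
      stop("non-numeric value in column '", cn, "' at row ",
           which(is.na(num) | !nzchar(tab[[cn]]))[1], call. = FALSE)
    tab[[cn]] <- num
  }
  tab$label <- trimws(tab$label)
  bad <- which(!(tab$label %in% LABEL_CODES))
  if (length(bad))
    stop("invalid label code '", tab$label[bad[1]], "' at row ", bad[1],
         " (allowed: C, D, N, E)", call. = FALSE)
  rownames(tab) <- NULL
  attr(tab, "source_id") <- id
  tab
}

#' Write a feature table as CSV (with header)
#'
#' @param table data.frame with columns `r`, `gv`, `GVSD`, `distAZ`, `label`.
#' @param path destination.
#' @return `path`, invisibly.
#' @export
write_feature_csv <- function(table, path) {
  stopifnot(all(c(FEATURE_COLS, "label") %in% names(table)))
  out <- table[, c(FEATURE_COLS, "label")]
  write.csv(out, path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' Write a color-coded classification stack
#'
#' Voxels of clear-core vesicles are painted magenta, dense-core vesicles
#' green, background black. A composite overlay on the original stack
#' (50/50 blend where a vesicle is present) is written alongside when
#' `original` is given.
#'
#' @param labels integer label array (`[y, x, z]`), 0 = background.
#' @param classes named character vector mapping label id to `"CCV"`/`"DCV"`.
#' @param path output TIFF (RGB); `NULL` to skip writing.
#' @param original optional [tomogram_stack()] for the composite overlay.
#' @param composite_path output TIFF of the overlay.
#' @return invisibly, a list with the RGB arrays `label_rgb` (and
#'   `composite_rgb` if requested), values in `[0, 255]`.
#' @export
write_color_label_stack <- function(labels, classes, path = NULL,
                                    original = NULL, composite_path = NULL) {
  ids <- sort(unique(labels[labels > 0]))
  missing <- setdiff(as.character(ids), names(classes))
  if (length(missing))
    stop("labels without class assignment: ", paste(missing, collapse = ", "),
         call. = FALSE)
  d <- dim(labels)
  rgb <- array(0, dim = c(d, 3L))
  cls <- classes[as.character(labels[labels > 0])]
  sel <- which(labels > 0)
  nvox <- prod(d)
  is_ccv <- cls == "CCV"
  rgb[sel[is_ccv]] <- 255                       # R
  rgb[sel[!is_ccv] + nvox] <- 255               # G
  rgb[sel[is_ccv] + 2 * nvox] <- 255            # B
  out <- list(label_rgb = rgb)
  if (!is.null(path)) write_rgb_tiff(rgb, path)
  if (!is.null(original)) {
    stopifnot(all(dim(original$voxels) == d))
    g <- original$voxels
    g <- if (max(g) > min(g)) (g - min(g)) / (max(g) - min(g)) * 255 else g * 0
    comp <- array(rep(g, 3L), dim = c(d, 3L))
    lab3 <- rep(labels > 0, 3L)
    comp[lab3] <- 0.5 * comp[lab3] + 0.5 * rgb[lab3]
    out$composite_rgb <- comp
    if (!is.null(composite_path)) write_rgb_tiff(comp, composite_path)
  }
  invisible(out)
}

write_rgb_tiff <- function(rgb, path) {
  d <- dim(rgb)
  pages <- lapply(seq_len(d[3]), function(z) rgb[, , z, ] / 255)
  tiff::writeTIFF(pages, path, bits.per.sample = 8L, compression = "none")
  invisible(path)
}

#' Write the classification result log
#'
#' One row per vesicle with all four features and the assigned class, plus a
#' footer with the per-class counts. In the log the class is serialized with
#' the numeric convention CCV = 1, DCV = 0 (training files use +1/-1; the
#' symbolic pair CCV/DCV is the canonical in-memory label everywhere).
#'
#' @param table classified feature table (columns `r`, `gv`, `GVSD`,
#'   `distAZ`, `class` with values `"CCV"`/`"DCV"`).
#' @param path destination text file.
#' @return `path`, invisibly.
#' @export
write_result_log <- function(table, path) {
  stopifnot(all(c(FEATURE_COLS, "class") %in% names(table)))
  code <- ifelse(table$class == "CCV", 1L, 0L)
  lines <- c("id\tr\tgv\tGVSD\tdistAZ\tclass\tcode",
             sprintf("%d\t%.6g\t%.6g\t%.6g\t%.6g\t%s\t%d",
                     seq_len(nrow(table)), table$r, table$gv, table$GVSD,
                     table$distAZ, table$class, code))
  n_ccv <- sum(table$class == "CCV")
  n_dcv <- sum(table$class == "DCV")
  lines <- c(lines, sprintf("# CCV: %d", n_ccv), sprintf("# DCV: %d", n_dcv),
             sprintf("# total: %d", n_ccv + n_dcv))
  writeLines(lines, path)
  invisible(path)
}

#' Re-parse a result log written by [write_result_log()]
#'
#' @param path log file.
#' @return data.frame with features, class and numeric code; attribute
#'   `counts` holds the footer counts (CCV, DCV).
#' @export
read_result_log <- function(path) {
  lines <- readLines(path)
  body <- lines[!startsWith(lines, "#")][-1]
  counts <- as.integer(sub("^# (CCV|DCV|total): ", "",
                           grep("^# (CCV|DCV):", lines, value = TRUE)))
  if (length(body) == 0L) {
    tab <- data.frame(id = integer(0), r = numeric(0), gv = numeric(0),
                      GVSD = numeric(0), distAZ = numeric(0),
                      class = character(0), code = integer(0))
  } else {
    tab <- read.delim(text = body, header = FALSE,
                      col.names = c("id", "r", "gv", "GVSD", "distAZ",
                                    "class", "code"))
  }
  attr(tab, "counts") <- c(CCV = counts[1], DCV = counts[2])
  tab
}
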