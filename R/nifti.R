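# Minimal NIfTI-1 reader/writer (.nii / .nii.gz, little-endian).
# Images are stored as float32, masks as uint8 so mask round trips are
# bit-exact. Only the fields this pipeline uses are honoured: dim, datatype,
# pixdim, vox_offset, scl_slope/inter and the sform row for the origin.

NIFTI_DT <- c(uint8 = 2L, int16 = 4L, int32 = 8L, float32 = 16L, float64 = 64L)

write_nifti_raw <- function(data, spacing, origin, path, datatype = "float32") {
  dims <- dim(data)
  ndim <- length(dims)
  stopifnot(ndim %in% c(3L, 4L))
  con <- if (grepl("\\.gz$", path)) gzfile(path, "wb") else file(path, "wb")
  on.exit(close(con))
  wi <- function(x, size) writeBin(as.integer(x), con, size = size, endian = "little")
  wf <- function(x) writeBin(as.numeric(x), con, size = 4, endian = "little")
  wi(348L, 4)                                   # sizeof_hdr
  writeBin(raw(36), con)                        # data_type..dim_info
  dim8 <- c(ndim, dims, rep(1L, 7 - ndim))
  wi(dim8, 2)                                   # dim[8]
  writeBin(raw(14), con)                        # intent params/codes
  dt <- NIFTI_DT[[datatype]]
  bitpix <- c(uint8 = 8L, int16 = 16L, int32 = 32L, float32 = 32L, float64 = 64L)[[datatype]]
  wi(dt, 2); wi(bitpix, 2); wi(0L, 2)           # datatype, bitpix, slice_start
  wf(c(1, spacing, rep(1, 7 - length(spacing))))  # pixdim[8]
  wf(352)                                       # vox_offset
  wf(1); wf(0)                                  # scl_slope, scl_inter
  writeBin(raw(4), con)                         # slice_end, slice_code, xyzt_units
  wf(c(0, 0, 0, 0))                             # cal_max, cal_min, slice_duration, toffset
  wi(0L, 4); wi(0L, 4)                          # glmax, glmin
  writeBin(charToRaw(sprintf("%-80s", "mlnet3d")), con)   # descrip[80]
  writeBin(raw(24), con)                        # aux_file[24]
  wi(0L, 2); wi(1L, 2)                          # qform_code=0, sform_code=1
  wf(rep(0, 6))                                 # quatern b,c,d + qoffset x,y,z
  wf(c(spacing[1], 0, 0, origin[1]))            # srow_x
  wf(c(0, spacing[2], 0, origin[2]))            # srow_y
  wf(c(0, 0, spacing[3], origin[3]))            # srow_z
  writeBin(raw(16), con)                        # intent_name[16]
  writeBin(c(charToRaw("n+1"), as.raw(0)), con) # magic
  writeBin(raw(4), con)                         # extension flag
  if (datatype == "uint8") {
    writeBin(as.raw(as.integer(data)), con)
  } else if (datatype %in% c("int16", "int32")) {
    writeBin(as.integer(data), con, size = bitpix / 8, endian = "little")
  } else {
    writeBin(as.numeric(data), con, size = bitpix / 8, endian = "little")
  }
  invisible(path)
}

read_nifti_raw <- function(path) {
  if (!file.exists(path)) stop("NIfTI file not found: ", path)
  con <- if (grepl("\\.gz$", path)) gzfile(path, "rb") else file(path, "rb")
  on.exit(close(con))
  hdr <- readBin(con, "raw", 348)
  if (length(hdr) < 348) stop("corrupt NIfTI header: ", path)
  ri <- function(off, size, n = 1)
    readBin(hdr[(off + 1):(off + size * n)], "integer", n = n, size = size,
            endian = "little")
  rf <- function(off, n = 1)
    readBin(hdr[(off + 1):(off + 4 * n)], "numeric", n = n, size = 4,
            endian = "little")
  if (ri(0, 4) != 348L) stop("not a NIfTI-1 file (bad sizeof_hdr): ", path)
  dim8 <- ri(40, 2, 8)
  ndim <- dim8[1]
  dims <- dim8[2:(1 + ndim)]
  datatype <- ri(70, 2)
  pixdim <- rf(76, 8)
  vox_offset <- rf(108)
  slope <- rf(112); inter <- rf(116)
  if (slope == 0) slope <- 1
  origin <- c(rf(280, 4)[4], rf(296, 4)[4], rf(312, 4)[4])
  skip <- vox_offset - 348
  if (skip > 0) readBin(con, "raw", skip)
  n <- prod(dims)
  data <- switch(as.character(datatype),
    "2" = as.numeric(readBin(con, "integer", n, size = 1, signed = FALSE)),
    "4" = as.numeric(readBin(con, "integer", n, size = 2, endian = "little")),
    "8" = as.numeric(readBin(con, "integer", n, size = 4, endian = "little")),
    "16" = readBin(con, "numeric", n, size = 4, endian = "little"),
    "64" = readBin(con, "numeric", n, size = 8, endian = "little"),
    stop("unsupported NIfTI datatype code: ", datatype))
  if (length(data) < n) stop("truncated NIfTI data: ", path)
  data <- data * slope + inter
  list(data = array(data, dims), spacing = pixdim[2:4], origin = origin)
}

#' Write a case to a directory as NIfTI plus a sidecar table
#'
#' Writes `image.nii.gz` (4D, float32), `mask.nii.gz` (uint8) and a
#' `case.csv` sidecar with the labels, centre and clinical covariates.
#'
#' @param case a `case_record`.
#' @param directory output directory (created if needed).
#' @return the directory, invisibly.
#' @export
write_nifti <- function(case, directory) {
  stopifnot(inherits(case, "case_record"))
  dir.create(directory, recursive = TRUE, showWarnings = FALSE)
  img <- case$image
  write_nifti_raw(img$data, img$spacing, img$origin,
                  file.path(directory, "image.nii.gz"), "float32")
  write_nifti_raw(case$mask$data, case$mask$spacing, img$origin,
                  file.path(directory, "mask.nii.gz"), "uint8")
  sc <- data.frame(patient_id = case$patient_id, centre_id = case$centre_id,
                   emvi = case$emvi_label, cr = case$cr_label, age = case$age,
                   sex = case$sex, cT = case$cT, cN = case$cN,
                   channels = paste(img$channel_names, collapse = ";"),
                   stringsAsFactors = FALSE)
  write.csv(sc, file.path(directory, "case.csv"), row.names = FALSE)
  invisible(directory)
}

#' Read a case written by [write_nifti]
#'
#' @param directory the case directory.
#' @return a `case_record` (generator geometry is not preserved on disk).
#' @export
read_nifti <- function(directory) {
  img <- read_nifti_raw(file.path(directory, "image.nii.gz"))
  msk <- read_nifti_raw(file.path(directory, "mask.nii.gz"))
  if (length(dim(img$data)) == 3L) dim(img$data) <- c(dim(img$data), 1L)
  if (!identical(dim(img$data)[1:3], dim(msk$data)[1:3]))
    stop("shape mismatch between image and mask")
  sc_path <- file.path(directory, "case.csv")
  if (!file.exists(sc_path)) stop("missing sidecar: ", sc_path)
  sc <- tryCatch(read.csv(sc_path, stringsAsFactors = FALSE,
                          colClasses = "character"),
                 error = function(e) stop("corrupt sidecar ", sc_path, ": ",
                                          conditionMessage(e)))
  need <- c("patient_id", "centre_id", "emvi", "cr", "age", "sex", "cT", "cN")
  if (!all(need %in% names(sc)) || nrow(sc) != 1L ||
      !all(c(sc$emvi, sc$cr) %in% c(0, 1)))
    stop("corrupt sidecar ", sc_path, ": missing or invalid fields")
  ch <- if ("channels" %in% names(sc)) strsplit(sc$channels, ";")[[1]] else NULL
  structure(list(patient_id = as.character(sc$patient_id),
                 centre_id = as.character(sc$centre_id),
                 image = volume_image(img$data, img$spacing, ch, img$origin),
                 mask = binary_mask(round(msk$data), msk$spacing),
                 emvi_label = as.integer(sc$emvi), cr_label = as.integer(sc$cr),
                 age = as.numeric(sc$age), sex = as.character(sc$sex),
                 cT = as.character(sc$cT), cN = as.character(sc$cN),
                 geometry = NULL),
            class = "case_record")
}

#' Write a cohort (one subdirectory per case plus a cohort sidecar)
#' @param cases list of `case_record` objects.
#' @param directory output directory.
#' @return the directory, invisibly.
#' @export
write_cohort <- function(cases, directory) {
  dir.create(directory, recursive = TRUE, showWarnings = FALSE)
  for (case in cases) write_nifti(case, file.path(directory, case$patient_id))
  write.csv(cohort_df(cases), file.path(directory, "cohort.csv"), row.names = FALSE)
  invisible(directory)
}

#' Read a cohort written by [write_cohort]
#' @param directory the cohort directory.
#' @return list of `case_record` objects.
#' @export
read_cohort <- function(directory) {
  sc_path <- file.path(directory, "cohort.csv")
  if (!file.exists(sc_path)) stop("missing cohort sidecar: ", sc_path)
  sc <- read.csv(sc_path, stringsAsFactors = FALSE)
  lapply(sc$patient_id, function(pid) read_nifti(file.path(directory, pid)))
}
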