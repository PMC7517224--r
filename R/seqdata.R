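#' Construct a cine sequence
#'
#' A `cine_sequence` holds N single-channel 2D frames spanning one motion
#' cycle (e.g. one cardiac cycle of a short-axis cine MRI slice). Frames are
#' stored as an `H x W x N` numeric array; the first array axis is the image
#' row (coordinate x1), the second the column (x2). After [preprocess()] the
#' intensities are jointly min-max normalized to `[0, 1]` over the whole
#' sequence (not per frame).
#'
#' @param frames numeric `H x W x N` array (a single `H x W` matrix is
#'   accepted and treated as N = 1, but most operations require N >= 2).
#' @param pixel_spacing isotropic pixel spacing in mm.
#' @param subject_id,slice_id opaque identifier strings.
#' @return an object of class `cine_sequence`.
#' @export
cine_sequence <- function(frames, pixel_spacing = 1, subject_id = "",
                          slice_id = "") {
  if (is.matrix(frames)) frames <- array(frames, c(dim(frames), 1L))
  if (!is.array(frames) || length(dim(frames)) != 3L)
    stop("`frames` must be an H x W x N array")
  if (!is.numeric(frames) || anyNA(frames))
    stop("`frames` must be numeric and free of NA")
  if (!is.numeric(pixel_spacing) || length(pixel_spacing) != 1L ||
      pixel_spacing <= 0)
    stop("`pixel_spacing` must be a positive scalar (mm)")
  structure(
    list(frames = frames, pixel_spacing = as.numeric(pixel_spacing),
         subject_id = as.character(subject_id),
         slice_id = as.character(slice_id)),
    class = "cine_sequence")
}

#' @export
print.cine_sequence <- function(x, ...) {
  d <- dim(x$frames)
  cat(sprintf(
    "<cine_sequence> %d frames of %d x %d px, spacing %.3g mm, range [%.3g, %.3g]\n",
    d[3], d[1], d[2], x$pixel_spacing, min(x$frames), max(x$frames)))
  invisible(x)
}

#' Number of frames in a cine sequence
#' @param seq a [cine_sequence()].
#' @return integer frame count.
#' @export
n_frames <- function(seq) {
  stopifnot(inherits(seq, "cine_sequence"))
  dim(seq$frames)[3]
}

frame_dim <- function(seq) dim(seq$frames)[1:2]

#' Construct a deformation sequence
#'
#' Per-frame dense displacement fields sampled on the template grid, in the
#' pull (backward-warping) convention: the registered value at template pixel
#' `x` is the frame sampled at `x + u(x)`. Displacements are in pixel units of
#' the (preprocessed) grid; component 1 displaces along rows (x1), component 2
#' along columns (x2). An all-zero array is the identity transform.
#'
#' @param displacements numeric `H x W x 2 x N` array.
#' @return an object of class `deformation_sequence`.
#' @export
deformation_sequence <- function(displacements) {
  if (!is.array(displacements) || length(dim(displacements)) != 4L ||
      dim(displacements)[3] != 2L)
    stop("`displacements` must be an H x W x 2 x N array")
  if (anyNA(displacements)) stop("`displacements` must be free of NA")
  structure(list(displacements = displacements),
            class = "deformation_sequence")
}

#' @export
print.deformation_sequence <- function(x, ...) {
  d <- dim(x$displacements)
  cat(sprintf(
    "<deformation_sequence> %d fields of %d x %d px, max |u| = %.3g px\n",
    d[4], d[1], d[2], max(abs(x$displacements))))
  invisible(x)
}

#' Construct a region mask
#'
#' Boolean mask selecting the template-domain region over which similarity,
#' regularization and constraint terms are accumulated (e.g. the cardiac
#' area). `NULL` everywhere in the package means "whole image".
#'
#' @param mask logical `H x W` matrix with at least one `TRUE` pixel.
#' @return an object of class `region_mask`.
#' @export
region_mask <- function(mask) {
  if (!is.matrix(mask) || !is.logical(mask))
    stop("`mask` must be a logical matrix")
  if (!any(mask)) stop("region mask must select at least one pixel")
  structure(list(mask = mask), class = "region_mask")
}

region_matrix <- function(region, dims) {
  if (is.null(region)) return(NULL)
  if (inherits(region, "region_mask")) region <- region$mask
  if (!all(dim(region) == dims))
    stop("region mask shape does not match image shape")
  region
}

check_seq_fields <- function(seq, fields) {
  d <- dim(fields$displacements)
  if (!all(d[c(1, 2, 4)] == dim(seq$frames)))
    stop("deformation sequence shape does not match cine sequence")
  invisible(TRUE)
}

# --- I/O -------------------------------------------------------------------

FIELD_AXIS_ORDER <- "(row, col, component, frame)"
FIELD_CONVENTION <- "pull: registered(x) = frame(x + u(x)); u in pixels"

guess_format <- function(path) {
  if (grepl("\\.nii(\\.gz)?$", path, ignore.case = TRUE)) return("nifti")
  if (grepl("\\.rds$", path, ignore.case = TRUE)) return("rds")
  if (dir.exists(path)) return("dicom_dir")
  stop("cannot guess format of ", path)
}

#' Load a cine sequence from disk
#'
#' Supported containers: NIfTI (`.nii`/`.nii.gz`, frames on the 3rd or 4th
#' dimension, spacing taken from the header) and RDS archives written by
#' [save_sequence()]. DICOM directories and NPZ/HDF5 archives are recognized
#' but not supported by this implementation and raise an error.
#'
#' @param path file path.
#' @param format one of `"auto"`, `"nifti"`, `"rds"`, `"dicom_dir"`,
#'   `"npz"`, `"hdf5"`.
#' @return a [cine_sequence()]; frames keep their stored (acquisition /
#'   cardiac-phase) order, no re-sorting is attempted.
#' @export
load_sequence <- function(path, format = "auto") {
  format <- match.arg(format, c("auto", "nifti", "rds", "dicom_dir", "npz",
                                "hdf5"))
  if (format == "auto") format <- guess_format(path)
  if (format %in% c("dicom_dir", "npz", "hdf5"))
    stop("format '", format, "' is not supported by this build; ",
         "use nifti or rds")
  if (!file.exists(path)) stop("file not found: ", path)
  if (format == "nifti") {
    img <- RNifti::readNifti(path)
    arr <- as.array(img)
    attributes(arr) <- list(dim = dim(arr))   # drop NIfTI metadata attrs
    if (length(dim(arr)) == 4L) {
      if (dim(arr)[3] == 1L) arr <- arr[, , 1, , drop = TRUE]
      else stop("multi-slice NIfTI volumes are not supported; ",
                "split slices into separate 2D sequences")
    }
    if (length(dim(arr)) != 3L)
      stop("NIfTI file does not contain a 2D dynamic sequence")
    sp <- tryCatch(RNifti::pixdim(img)[1], error = function(e) 1)
    if (!is.finite(sp) || sp <= 0) sp <- 1
    return(cine_sequence(arr, pixel_spacing = sp,
                         subject_id = basename(path)))
  }
  obj <- readRDS(path)
  if (!is.list(obj) || is.null(obj$frames))
    stop("RDS file does not contain a cine sequence archive")
  cine_sequence(obj$frames,
                pixel_spacing = obj$pixel_spacing %||% 1,
                subject_id = obj$subject_id %||% "",
                slice_id = obj$slice_id %||% "")
}

#' Save a cine sequence
#'
#' @param seq a [cine_sequence()].
#' @param path destination; extension selects the container (`.nii`/`.nii.gz`
#'   or `.rds`).
#' @return `path`, invisibly.
#' @export
save_sequence <- function(seq, path) {
  stopifnot(inherits(seq, "cine_sequence"))
  fmt <- guess_format(path)
  if (fmt == "nifti") {
    img <- RNifti::asNifti(seq$frames)
    RNifti::pixdim(img) <- c(seq$pixel_spacing, seq$pixel_spacing, 1)
    RNifti::writeNifti(img, path)
  } else if (fmt == "rds") {
    saveRDS(list(frames = seq$frames, pixel_spacing = seq$pixel_spacing,
                 subject_id = seq$subject_id, slice_id = seq$slice_id,
                 axis_order = "(row, col, frame)"),
            path)
  } else stop("cannot write format '", fmt, "'")
  invisible(path)
}

#' Save / load deformation fields
#'
#' Fields are archived (RDS) together with metadata strings recording the
#' axis order `(row, col, component, frame)` and the pull-warp displacement
#' convention, so archives are self-describing.
#'
#' @param fields a [deformation_sequence()].
#' @param path destination `.rds` path.
#' @return `path` invisibly (`save_fields`); a [deformation_sequence()]
#'   (`load_fields`).
#' @export
save_fields <- function(fields, path) {
  stopifnot(inherits(fields, "deformation_sequence"))
  saveRDS(list(displacements = fields$displacements,
               axis_order = FIELD_AXIS_ORDER,
               convention = FIELD_CONVENTION),
          path)
  invisible(path)
}

#' @rdname save_fields
#' @param seq optional paired [cine_sequence()]; when given, the loaded field
#'   shape is validated against it.
#' @export
load_fields <- function(path, seq = NULL) {
  if (!file.exists(path)) stop("file not found: ", path)
  obj <- readRDS(path)
  if (!is.list(obj) || is.null(obj$displacements))
    stop("RDS file does not contain a deformation-field archive")
  fields <- deformation_sequence(obj$displacements)
  if (!is.null(seq)) check_seq_fields(seq, fields)
  fields
}

# --- preprocessing ---------------------------------------------------------

#' Jointly min-max normalize a sequence to [0, 1]
#'
#' Sequence-level normalization: one min and one max over all frames, so
#' relative intensities across frames are preserved. A constant sequence
#' (min == max) maps to all zeros. Affine intensity changes a*I + b (a > 0)
#' of the input yield the same normalized output.
#'
#' @param seq a [cine_sequence()].
#' @return normalized [cine_sequence()].
#' @export
normalize_sequence <- function(seq) {
  stopifnot(inherits(seq, "cine_sequence"))
  lo <- min(seq$frames); hi <- max(seq$frames)
  seq$frames <- if (hi > lo) (seq$frames - lo) / (hi - lo)
                else array(0, dim(seq$frames))
  seq
}

# bilinear resize of one matrix to target dims (align corner centers at the
# image borders; sampling grid expressed in source pixel coordinates)
resize_bilinear <- function(img, out_h, out_w) {
  h <- nrow(img); w <- ncol(img)
  if (out_h == h && out_w == w) return(img)
  r <- if (out_h == 1) rep((h + 1) / 2, 1) else seq(1, h, length.out = out_h)
  c_ <- if (out_w == 1) rep((w + 1) / 2, 1) else seq(1, w, length.out = out_w)
  r0 <- pmin(floor(r), h - 1L); fr <- r - r0
  c0 <- pmin(floor(c_), w - 1L); fc <- c_ - c0
  if (h == 1) { r0 <- rep(1, out_h); fr <- rep(0, out_h) }
  if (w == 1) { c0 <- rep(1, out_w); fc <- rep(0, out_w) }
  a <- img[r0, c0, drop = FALSE]; b <- img[r0 + (h > 1), c0, drop = FALSE]
  cc <- img[r0, c0 + (w > 1), drop = FALSE]
  d <- img[r0 + (h > 1), c0 + (w > 1), drop = FALSE]
  fr <- matrix(fr, out_h, out_w); fc <- matrix(fc, out_h, out_w, byrow = TRUE)
  (1 - fr) * (1 - fc) * a + fr * (1 - fc) * b +
    (1 - fr) * fc * cc + fr * fc * d
}

crop_or_pad <- function(img, size) {
  h <- nrow(img); w <- ncol(img)
  out <- matrix(0, size, size)
  # source and destination index windows for a central crop / zero pad
  src_r <- max(1, floor((h - size) / 2) + 1); n_r <- min(h, size)
  src_c <- max(1, floor((w - size) / 2) + 1); n_c <- min(w, size)
  dst_r <- max(1, floor((size - h) / 2) + 1)
  dst_c <- max(1, floor((size - w) / 2) + 1)
  out[dst_r:(dst_r + n_r - 1), dst_c:(dst_c + n_c - 1)] <-
    img[src_r:(src_r + n_r - 1), src_c:(src_c + n_c - 1)]
  out
}

#' Preprocess a cine sequence
#'
#' Resamples every frame to the target isotropic spacing (bilinear), centrally
#' crops (or zero-pads) to `crop_size x crop_size`, and jointly min-max
#' normalizes the sequence to `[0, 1]`. Idempotent for already-conforming
#' input.
#'
#' @param seq a [cine_sequence()].
#' @param target_spacing_mm output pixel spacing in mm (default 1).
#' @param crop_size output side length in pixels (default 320).
#' @return preprocessed [cine_sequence()].
#' @export
preprocess <- function(seq, target_spacing_mm = 1, crop_size = 320) {
  stopifnot(inherits(seq, "cine_sequence"))
  if (!is.numeric(target_spacing_mm) || target_spacing_mm <= 0)
    stop("`target_spacing_mm` must be positive")
  if (crop_size < 8) stop("`crop_size` must be >= 8")
  d <- dim(seq$frames)
  scale <- seq$pixel_spacing / target_spacing_mm
  out_h <- max(1L, as.integer(round(d[1] * scale)))
  out_w <- max(1L, as.integer(round(d[2] * scale)))
  frames <- array(0, c(crop_size, crop_size, d[3]))
  for (n in seq_len(d[3])) {
    f <- seq$frames[, , n]
    if (out_h != d[1] || out_w != d[2]) f <- resize_bilinear(f, out_h, out_w)
    frames[, , n] <- crop_or_pad(f, crop_size)
  }
  normalize_sequence(cine_sequence(frames, pixel_spacing = target_spacing_mm,
                                   subject_id = seq$subject_id,
                                   slice_id = seq$slice_id))
}

`%||%` <- function(a, b) if (is.null(a)) b else a
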