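## label_io: reading segmentation label volumes, selecting and merging the
## body subfields, molecular-layer reassignment, head/tail cropping, closure.

canonicalLabelNames <- c("presubiculum", "subiculum", "CA1", "CA2", "CA3",
                         "CA4", "DG", "molecular_layer", "head", "tail")
bodySubfieldNames <- c("presubiculum", "subiculum", "CA1", "CA2", "CA3")

#' Label dialect tables
#'
#' A dialect maps the canonical anatomical names (presubiculum, subiculum,
#' CA1, CA2, CA3, CA4, DG, molecular_layer, head, tail) to the integer codes
#' a segmentation tool writes. Built-in tables (shipped as editable TSV under
#' `inst/extdata/dialects/`) cover the FreeSurfer hippocampal-subfield
#' module, the ASHS Penn ABC-3T atlas, and the synthetic phantom. A path to
#' a custom two-column TSV (name, code) is also accepted wherever a dialect
#' name is.
#'
#' @param dialect dialect name ("freesurfer", "ashs", "phantom") or a path
#'   to a TSV file.
#' @return named integer vector (name -> code).
#' @export
labelDialectTable <- function(dialect) {
  builtin <- c("freesurfer", "ashs", "phantom")
  path <- if (dialect %in% builtin) {
    system.file("extdata", "dialects", paste0(dialect, ".tsv"),
                package = "hipposheet", mustWork = TRUE)
  } else if (file.exists(dialect)) {
    dialect
  } else {
    hsError("label_io", "unknown dialect '%s' (not built-in, not a file)",
            dialect)
  }
  tab <- utils::read.table(path, header = TRUE, sep = "\t",
                           stringsAsFactors = FALSE)
  bad <- setdiff(tab$name, canonicalLabelNames)
  if (length(bad))
    hsError("label_io", "dialect file %s contains unknown names: %s",
            path, paste(bad, collapse = ", "))
  stats::setNames(as.integer(tab$code), tab$name)
}

## Minimal reader for FreeSurfer MGH/MGZ volumes (big-endian; gzipped when
## .mgz). Only what a label volume needs: dims, data type, vox2ras.
readMGZ <- function(path) {
  con <- if (grepl("\\.mgz$", path)) gzfile(path, "rb") else file(path, "rb")
  on.exit(close(con))
  rdi <- function(n) readBin(con, integer(), n, size = 4, endian = "big")
  rds <- function(n) readBin(con, integer(), n, size = 2, endian = "big")
  rdf <- function(n) readBin(con, numeric(), n, size = 4, endian = "big")
  version <- rdi(1)
  if (!identical(version, 1L))
    hsError("label_io", "not an MGH/MGZ file (version %d)", version)
  dims <- rdi(4)                        # width, height, depth, nframes
  dtype <- rdi(1)
  rdi(1)                                # dof, unused
  goodRAS <- rds(1)
  bytesRead <- 4L * 7L + 2L
  if (goodRAS > 0) {
    spacing <- rdf(3)
    Mdc <- matrix(rdf(9), 3, 3)         # columns = x, y, z axes
    cras <- rdf(3)
    bytesRead <- bytesRead + 4L * 15L
  } else {
    spacing <- c(1, 1, 1); Mdc <- diag(3); cras <- c(0, 0, 0)
  }
  readBin(con, raw(), 284L - bytesRead)  # remainder of the fixed header
  nvox <- prod(dims[1:3]) * max(1L, dims[4])
  data <- switch(as.character(dtype),
    "0" = as.numeric(readBin(con, integer(), nvox, size = 1, signed = FALSE)),
    "1" = as.numeric(readBin(con, integer(), nvox, size = 4, endian = "big")),
    "3" = readBin(con, numeric(), nvox, size = 4, endian = "big"),
    "4" = as.numeric(readBin(con, integer(), nvox, size = 2, endian = "big")),
    hsError("label_io", "unsupported MGH data type %d", dtype))
  arr <- array(data[seq_len(prod(dims[1:3]))], dims[1:3])
  A <- diag(4)
  A[1:3, 1:3] <- Mdc %*% diag(spacing)
  A[1:3, 4] <- cras - A[1:3, 1:3] %*% (dims[1:3] / 2)
  list(data = arr, affine = A)
}

#' Load a segmentation label volume
#'
#' Reads a NIfTI (`.nii`/`.nii.gz`) or FreeSurfer MGH/MGZ label image
#' without resampling, keeping the header affine. Non-integral voxel values
#' are an error; codes absent from the dialect are kept but reported in a
#' warning.
#'
#' @param path path to the label image.
#' @param dialect dialect name or TSV path, see [labelDialectTable()].
#' @return a [LabelVolume-class].
#' @export
loadLabelVolume <- function(path, dialect = "freesurfer") {
  if (!file.exists(path))
    hsError("label_io", "file not found: %s", path)
  labels <- labelDialectTable(dialect)
  if (grepl("\\.mg[hz]$", path)) {
    r <- readMGZ(path)
    arr <- r$data; aff <- r$affine
  } else {
    img <- RNifti::readNifti(path)
    aff <- structure(RNifti::xform(img), imagedim = NULL, code = NULL)
    aff <- matrix(as.numeric(aff), 4, 4)
    arr <- array(as.numeric(img), dim(img)[1:3])
  }
  if (max(abs(arr - round(arr))) > 1e-6)
    hsError("label_io", "volume contains non-integral label values")
  arr <- array(as.integer(round(arr)), dim(arr))
  vol <- new("LabelVolume", data = arr, affine = aff,
             dialect = if (file.exists(dialect)) "custom" else dialect,
             labels = labels)
  unknown <- setdiff(unique(arr[arr > 0]), labels)
  if (length(unknown))
    warning(sprintf("codes not in dialect '%s' (ignored): %s", vol@dialect,
                    paste(sort(unknown), collapse = ", ")), call. = FALSE)
  vol
}

#' Write a label volume as NIfTI
#'
#' @param vol a [LabelVolume-class].
#' @param path output path (`.nii` or `.nii.gz`).
#' @return `path`, invisibly.
#' @export
writeLabelVolume <- function(vol, path) {
  img <- RNifti::asNifti(vol@data)
  RNifti::sform(img) <- structure(vol@affine, code = 2L)
  RNifti::writeNifti(img, path)
  invisible(path)
}

## in-plane voxel sizes (mm per voxel step along each voxel axis)
voxelSizes <- function(affine) sqrt(colSums(affine[1:3, 1:3]^2))

## slice indices along `axis` containing any of `codes`
slicesWithCodes <- function(lab, codes, axis) {
  hit <- array(lab %in% codes, dim(lab))
  which(apply(hit, axis, any))
}

#' Prepare the binary hippocampal body mask
#'
#' Implements the shape-definition step: molecular-layer voxels are
#' reassigned to the nearest body subfield (Euclidean distance in world mm,
#' ties to the lowest code), the anterior/posterior extent of the body is
#' determined from head/tail labels where present (otherwise from the most
#' anterior slice carrying CA2 or CA3 and the most posterior slice carrying
#' CA1 together with CA2/CA3), the body subfields inside those limits are
#' binarized, and small holes and protrusions are corrected by a repeated
#' morphological closure (6-connected structuring element).
#'
#' @param vol a [LabelVolume-class].
#' @param closureIterations number of dilation/erosion rounds (default 2).
#' @return a [BodyMask-class].
#' @export
prepareBodyMask <- function(vol, closureIterations = 2L) {
  lab <- vol@data
  L <- vol@labels
  voxdim <- voxelSizes(vol@affine)
  bodyCodes <- unique(unname(L[intersect(bodySubfieldNames, names(L))]))
  if (!length(bodyCodes) || !any(lab %in% bodyCodes))
    hsError("label_io", "no hippocampal body subfield voxels present")

  ## molecular-layer reassignment (count-preserving)
  if ("molecular_layer" %in% names(L) && any(lab == L[["molecular_layer"]])) {
    nearest <- nearestLabelMap(lab, bodyCodes, voxdim)
    ml <- lab == L[["molecular_layer"]]
    lab[ml] <- nearest[ml]
  }

  ## anterior/posterior axis: voxel axis most aligned with world y
  apAxis <- which.max(abs(vol@affine[2, 1:3]))
  anteriorEnd <- if (vol@affine[2, apAxis] >= 0) 2L else 1L

  ca23 <- unique(unname(L[intersect(c("CA2", "CA3"), names(L))]))
  ca1 <- unname(L[intersect("CA1", names(L))])
  if (!length(ca23) || !any(lab %in% ca23))
    hsError("label_io", "no CA2/CA3 voxels: anterior limit undefined")

  antLimit <- function() {
    if ("head" %in% names(L) && any(lab == L[["head"]])) {
      hs <- slicesWithCodes(lab, L[["head"]], apAxis)
      if (anteriorEnd == 2L) min(hs) - 1L else max(hs) + 1L
    } else {
      s <- slicesWithCodes(lab, ca23, apAxis)
      if (anteriorEnd == 2L) max(s) else min(s)
    }
  }
  postLimit <- function() {
    if ("tail" %in% names(L) && any(lab == L[["tail"]])) {
      ts <- slicesWithCodes(lab, L[["tail"]], apAxis)
      if (anteriorEnd == 2L) max(ts) + 1L else min(ts) - 1L
    } else {
      s <- intersect(slicesWithCodes(lab, ca1, apAxis),
                     slicesWithCodes(lab, ca23, apAxis))
      if (!length(s))
        hsError("label_io", "no slice carries CA1 together with CA2/CA3")
      if (anteriorEnd == 2L) min(s) else max(s)
    }
  }
  lims <- sort(c(antLimit(), postLimit()))
  lo <- lims[1]; hi <- lims[2]

  mask <- array(lab %in% bodyCodes, dim(lab))
  keep <- rep(FALSE, dim(lab)[apAxis]); keep[lo:hi] <- TRUE
  mask <- mask & slice1d(dim(lab), apAxis, keep)
  if (!any(mask))
    hsError("label_io", "empty body mask after anterior/posterior cropping")
  mask <- closeMask(mask, as.integer(closureIterations))
  mask <- mask & slice1d(dim(lab), apAxis, keep)

  new("BodyMask", mask = mask, affine = vol@affine, apAxis = apAxis,
      apRange = c(lo, hi), anteriorEnd = anteriorEnd)
}

## logical array that is TRUE on the slices `keep` along `axis`
slice1d <- function(dims, axis, keep) {
  a <- array(FALSE, dims)
  idx <- which(keep)
  if (axis == 1L) a[idx, , ] <- TRUE
  else if (axis == 2L) a[, idx, ] <- TRUE
  else a[, , idx] <- TRUE
  a
}

#' Topology report for a body mask
#'
#' Reports the number of 6-connected foreground components, the number of
#' 26-connected background components (one means no internal cavity), and
#' the Euler characteristic of the boundary surface (2 for a genus-0
#' solid), computed from the cubical complex. The `fatal` flag marks masks
#' the pipeline refuses to process (disconnected foreground or internal
#' cavities), matching the documented failure behavior on topologically
#' defective segmentations.
#'
#' @param m a [BodyMask-class].
#' @return list with `nComponents`, `nBackgroundComponents`,
#'   `eulerBoundary`, `fatal`.
#' @export
checkMaskTopology <- function(m) {
  mask <- m@mask
  fg <- arrayComponents(mask, 6L)
  pad <- array(FALSE, dim(mask) + 2L)
  pad[1 + seq_len(dim(mask)[1]), 1 + seq_len(dim(mask)[2]),
      1 + seq_len(dim(mask)[3])] <- mask
  bg <- arrayComponents(!pad, 26L)
  ## Euler characteristic of the voxel complex: V - E + F - C
  n <- dim(mask)
  orAcc <- function(dims, shifts) {
    a <- array(FALSE, dims)
    for (s in shifts) {
      i1 <- s[1] + seq_len(n[1]); i2 <- s[2] + seq_len(n[2])
      i3 <- s[3] + seq_len(n[3])
      a[i1, i2, i3] <- a[i1, i2, i3] | mask
    }
    sum(a)
  }
  offs <- function(k) if (k) 0:1 else 0
  cnt <- function(ox, oy, oz) {
    sh <- list()
    for (a in offs(ox)) for (b in offs(oy)) for (c in offs(oz))
      sh <- c(sh, list(c(a, b, c)))
    orAcc(n + c(ox, oy, oz), sh)
  }
  V <- cnt(1, 1, 1)
  E <- cnt(0, 1, 1) + cnt(1, 0, 1) + cnt(1, 1, 0)
  F <- cnt(1, 0, 0) + cnt(0, 1, 0) + cnt(0, 0, 1)
  C <- sum(mask)
  chi <- V - E + F - C
  list(nComponents = fg$n, nBackgroundComponents = bg$n,
       eulerBoundary = 2L * chi,
       fatal = fg$n != 1L || bg$n > 1L)
}
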