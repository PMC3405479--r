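#' Read and write volumes as MetaImage (.mha)
#'
#' Uncompressed single-file MetaImage with local raw data: the standard
#' exchange format for registration toolkits. Intensities are written as
#' 32-bit float (\code{MET_FLOAT}); masks can be round-tripped by writing
#' their 0/1 data.
#'
#' @param volume an \code{image_volume}.
#' @param path file path ending in .mha.
#' @return \code{read_metaimage} returns an \code{image_volume}.
#' @export
write_metaimage <- function(volume, path) {
  stopifnot(is_image_volume(volume))
  d <- vol_dim(volume)
  hdr <- c("ObjectType = Image",
           "NDims = 3",
           "BinaryData = True",
           "BinaryDataByteOrderMSB = False",
           "CompressedData = False",
           "TransformMatrix = 1 0 0 0 1 0 0 0 1",
           paste("Offset =", paste(volume$origin, collapse = " ")),
           "CenterOfRotation = 0 0 0",
           "AnatomicalOrientation = RAI",
           paste("ElementSpacing =", paste(volume$spacing, collapse = " ")),
           paste("DimSize =", paste(d, collapse = " ")),
           "ElementType = MET_FLOAT",
           "ElementDataFile = LOCAL")
  con <- file(path, "wb")
  on.exit(close(con))
  writeLines(hdr, con)
  writeBin(as.numeric(volume$data), con, size = 4, endian = "little")
  invisible(path)
}

#' @rdname write_metaimage
#' @export
read_metaimage <- function(path) {
  con <- file(path, "rb")
  on.exit(close(con))
  hdr <- list()
  repeat {
    line <- readLines(con, n = 1)
    if (!length(line)) stop("unexpected end of MetaImage header")
    kv <- strsplit(line, "=", fixed = TRUE)[[1]]
    key <- trimws(kv[1])
    hdr[[key]] <- trimws(paste(kv[-1], collapse = "="))
    if (key == "ElementDataFile") break
  }
  if (!identical(hdr$ElementDataFile, "LOCAL"))
    stop("only LOCAL-data MetaImage files are supported")
  if (!identical(hdr$CompressedData %||% "False", "False"))
    stop("compressed MetaImage is not supported")
  d <- as.integer(strsplit(hdr$DimSize, "\\s+")[[1]])
  spacing <- as.numeric(strsplit(hdr$ElementSpacing %||% "1 1 1",
                                 "\\s+")[[1]])
  origin <- as.numeric(strsplit(hdr$Offset %||% "0 0 0", "\\s+")[[1]])
  type <- hdr$ElementType
  n <- prod(d)
  v <- switch(type,
              MET_FLOAT = readBin(con, numeric(), n, size = 4,
                                  endian = "little"),
              MET_DOUBLE = readBin(con, numeric(), n, size = 8,
                                   endian = "little"),
              MET_SHORT = readBin(con, integer(), n, size = 2,
                                  endian = "little"),
              MET_UCHAR = as.numeric(readBin(con, integer(), n, size = 1,
                                             signed = FALSE)),
              stop("unsupported ElementType: ", type))
  image_volume(array(as.numeric(v), d), spacing, origin)
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Read and write volumes as uncompressed NIfTI-1 (.nii)
#'
#' Minimal single-file NIfTI-1 support (float32, no orientation matrix
#' beyond spacing/origin via qoffset with an identity rotation). Intended
#' for exchanging volumes, masks (0/1) and displacement fields with other
#' neuroimaging/radiotherapy tools.
#'
#' @param volume an \code{image_volume}.
#' @param path file path ending in .nii.
#' @return \code{read_nifti} returns an \code{image_volume}.
#' @export
write_nifti <- function(volume, path) {
  stopifnot(is_image_volume(volume))
  d <- vol_dim(volume)
  con <- file(path, "wb")
  on.exit(close(con))
  w_i <- function(x, size) writeBin(as.integer(x), con, size = size,
                                    endian = "little")
  w_f <- function(x, size = 4) writeBin(as.numeric(x), con, size = size,
                                        endian = "little")
  w_raw <- function(n) writeBin(raw(n), con)
  w_i(348, 4)                      # sizeof_hdr
  w_raw(36)                        # unused legacy fields
  w_i(c(3, d, 1, 1, 1, 1), 2)      # dim[8]
  w_f(c(0, 0, 0))                  # intent params
  w_i(0, 2)                        # intent_code
  w_i(16, 2)                       # datatype: float32
  w_i(32, 2)                       # bitpix
  w_i(0, 2)                        # slice_start
  w_f(c(0, volume$spacing, 0, 0, 0, 0))  # pixdim[8] (qfac 0 -> treated as 1)
  w_f(352)                         # vox_offset
  w_f(c(1, 0))                     # scl_slope, scl_inter
  w_i(0, 2); w_i(0, 1); w_i(0, 1)  # slice_end, slice_code, xyzt_units
  w_f(c(0, 0, 0))                  # cal_max, cal_min, slice_duration
  w_f(0)                           # toffset
  w_i(c(0, 0), 4)                  # glmax, glmin
  w_raw(80 + 24)                   # descrip, aux_file
  w_i(c(0, 1), 2)                  # qform_code 0, sform_code 1
  w_f(c(0, 0, 0, 0, 0, 0))         # quaternions + qoffset
  w_f(c(volume$spacing[1], 0, 0, volume$origin[1]))  # srow_x
  w_f(c(0, volume$spacing[2], 0, volume$origin[2]))  # srow_y
  w_f(c(0, 0, volume$spacing[3], volume$origin[3]))  # srow_z
  w_raw(16)                        # intent_name
  writeChar("n+1", con, nchars = 3, eos = NULL)
  w_raw(1)                         # magic terminator
  w_raw(4)                         # extension flag
  w_f(as.numeric(volume$data))
  invisible(path)
}

#' @rdname write_nifti
#' @export
read_nifti <- function(path) {
  con <- file(path, "rb")
  on.exit(close(con))
  r_i <- function(n, size) readBin(con, integer(), n, size = size,
                                   endian = "little")
  r_f <- function(n, size = 4) readBin(con, numeric(), n, size = size,
                                       endian = "little")
  if (r_i(1, 4) != 348) stop("not a little-endian NIfTI-1 file")
  invisible(readBin(con, raw(), 36))
  dim8 <- r_i(8, 2)
  if (dim8[1] != 3) stop("only 3D NIfTI volumes are supported")
  d <- dim8[2:4]
  r_f(3); r_i(1, 2)
  datatype <- r_i(1, 2)
  r_i(2, 2)
  pixdim <- r_f(8)
  vox_offset <- r_f(1)
  r_f(2); r_i(1, 2); readBin(con, raw(), 2)
  r_f(4)
  r_i(2, 4)
  invisible(readBin(con, raw(), 104))
  r_i(2, 2)
  r_f(6)
  srow <- matrix(r_f(12), 3, 4, byrow = TRUE)
  origin <- srow[, 4]
  spacing <- pixdim[2:4]
  seek(con, vox_offset)
  n <- prod(d)
  v <- switch(as.character(datatype),
              "16" = r_f(n),
              "64" = r_f(n, 8),
              "4" = as.numeric(r_i(n, 2)),
              "2" = as.numeric(readBin(con, integer(), n, size = 1,
                                       signed = FALSE)),
              stop("unsupported NIfTI datatype: ", datatype))
  image_volume(array(v, d), spacing, origin)
}

#' Write a displacement field as a 4-component NIfTI-like stack
#'
#' The three components are written as three .nii volumes with suffixes
#' _x/_y/_z (a single 5D vector NIfTI would not round-trip through the
#' minimal 3D reader here).
#'
#' @param dvf a \code{displacement_field}.
#' @param prefix path prefix; files \code{<prefix>_x.nii} etc. are written.
#' @return \code{read_dvf_nifti} returns a \code{displacement_field}.
#' @export
write_dvf_nifti <- function(dvf, prefix) {
  for (cmp in c("x", "y", "z"))
    write_nifti(image_volume(dvf[[paste0("v", cmp)]], dvf$spacing,
                             dvf$origin),
                paste0(prefix, "_", cmp, ".nii"))
  invisible(prefix)
}

#' @rdname write_dvf_nifti
#' @export
read_dvf_nifti <- function(prefix) {
  v <- lapply(c("x", "y", "z"), function(cmp)
    read_nifti(paste0(prefix, "_", cmp, ".nii")))
  displacement_field(v[[1]]$data, v[[2]]$data, v[[3]]$data,
                     v[[1]]$spacing, v[[1]]$origin)
}

#' Read and write a mask as NIfTI (0/1 labels)
#' @param mask a \code{binary_mask}.
#' @param path .nii path.
#' @param label label for the mask read back.
#' @return \code{read_mask_nifti} returns a \code{binary_mask}.
#' @export
write_mask_nifti <- function(mask, path) {
  write_nifti(image_volume(mask$data * 1, mask$spacing, mask$origin), path)
}

#' @rdname write_mask_nifti
#' @export
read_mask_nifti <- function(path, label = "roi") {
  v <- read_nifti(path)
  binary_mask(v$data > 0.5, v$spacing, v$origin, label)
}

#' Read and write surface meshes as ASCII PLY
#' @param mesh a \code{surface_mesh}.
#' @param path .ply path.
#' @param label label for the mesh read back.
#' @return \code{read_ply} returns a \code{surface_mesh}.
#' @export
write_ply <- function(mesh, path) {
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(c("ply", "format ascii 1.0",
               paste("element vertex", nrow(mesh$vertices)),
               "property float x", "property float y", "property float z",
               paste("element face", nrow(mesh$triangles)),
               "property list uchar int vertex_indices", "end_header"),
             con)
  utils::write.table(format(mesh$vertices, trim = TRUE, digits = 10),
                     con, row.names = FALSE, col.names = FALSE,
                     quote = FALSE)
  utils::write.table(cbind(3L, mesh$triangles - 1L), con,
                     row.names = FALSE, col.names = FALSE, quote = FALSE)
  invisible(path)
}

#' @rdname write_ply
#' @export
read_ply <- function(path, label = "roi") {
  lines <- readLines(path)
  if (lines[1] != "ply" || !grepl("ascii", lines[2]))
    stop("only ASCII PLY is supported")
  nv <- as.integer(sub("element vertex ", "",
                       grep("^element vertex", lines, value = TRUE)[1]))
  nf <- as.integer(sub("element face ", "",
                       grep("^element face", lines, value = TRUE)[1]))
  h <- which(lines == "end_header")
  verts <- do.call(rbind, lapply(strsplit(lines[h + seq_len(nv)], "\\s+"),
                                 as.numeric))
  faces <- do.call(rbind,
                   lapply(strsplit(lines[h + nv + seq_len(nf)], "\\s+"),
                          as.integer))
  if (any(faces[, 1] != 3L)) stop("only triangle faces are supported")
  surface_mesh(verts[, 1:3], faces[, 2:4] + 1L, label)
}
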