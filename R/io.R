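## Coordinate and table I/O: PDB (via bio3d), GRO and XYZ fixed-column
## writers, label maps as text matrix or PNG, tidy CSV outputs.

#' Write a frame set frame (or all frames) as PDB
#'
#' Single frames are written as a plain PDB; multi-frame sets as a
#' concatenated MODEL/ENDMDL file.
#'
#' @param fs a `frame_set`.
#' @param path output path.
#' @param frames frame indices (default all).
#' @export
write_pdb_frames <- function(fs, path, frames = seq_len(n_frames(fs))) {
  na <- nrow(fs$atoms)
  xyz <- do.call(rbind, lapply(frames, function(k) as.vector(t(fs$coords[, , k]))))
  bio3d::write.pdb(
    file = path,
    xyz = if (length(frames) == 1) xyz[1, ] else xyz,
    type = rep("ATOM", na),
    resno = fs$atoms$resid,
    resid = substr(paste0(fs$atoms$restype, "  "), 1, 3),
    eleno = seq_len(na),
    elety = fs$atoms$name,
    chain = rep("A", na)
  )
  invisible(path)
}

#' Read a (multi-model) PDB into a frame set
#'
#' @param path PDB path.
#' @param box box lengths to attach (PDB written here carries none).
#' @param frame_interval ns between models.
#' @export
read_pdb_frames <- function(path, box = c(100, 100, 100), frame_interval = 1) {
  pdb <- bio3d::read.pdb(path, multi = TRUE)
  xyz <- pdb$xyz
  if (is.null(dim(xyz))) xyz <- matrix(xyz, nrow = 1)
  nfr <- nrow(xyz)
  na <- ncol(xyz) / 3
  coords <- array(NA_real_, c(na, 3, nfr))
  for (k in seq_len(nfr)) coords[, , k] <- matrix(xyz[k, ], ncol = 3, byrow = TRUE)
  atoms <- data.frame(
    name = pdb$atom$elety, element = substr(pdb$atom$elety, 1, 1),
    role = ifelse(pdb$atom$resid == "HOH",
                  ifelse(substr(pdb$atom$elety, 1, 1) == "O", "water_O", "water_H"),
                  ifelse(pdb$atom$resid == "PRB", "probe", "peptide")),
    mol_id = pdb$atom$resno, resid = pdb$atom$resno, restype = pdb$atom$resid
  )
  frame_set(coords, atoms, box, times = (seq_len(nfr) - 1) * frame_interval)
}

#' Write a frame set as XYZ
#'
#' Plain XYZ: atom count line, comment line with the time stamp, then
#' `element x y z` rows per frame, frames concatenated.
#'
#' @param fs a `frame_set`.
#' @param path output path.
#' @param frames frame indices (default all).
#' @export
write_xyz <- function(fs, path, frames = seq_len(n_frames(fs))) {
  con <- file(path, "w")
  on.exit(close(con))
  na <- nrow(fs$atoms)
  for (k in frames) {
    writeLines(c(as.character(na), sprintf("t = %.6f ns", fs$times[k])), con)
    x <- fs$coords[, , k, drop = TRUE]
    writeLines(sprintf("%-3s %12.6f %12.6f %12.6f",
                       fs$atoms$element, x[, 1], x[, 2], x[, 3]), con)
  }
  invisible(path)
}

#' Read an XYZ trajectory
#'
#' @param path XYZ path written by [write_xyz()] (or compatible).
#' @param box box lengths to attach.
#' @export
read_xyz <- function(path, box = c(100, 100, 100)) {
  lines <- readLines(path)
  frames <- list(); times <- numeric()
  i <- 1
  while (i <= length(lines)) {
    na <- as.integer(lines[i])
    tm <- suppressWarnings(as.numeric(sub(".*t = ([0-9.eE+-]+) ns.*", "\\1",
                                          lines[i + 1])))
    block <- lines[(i + 2):(i + 1 + na)]
    parts <- strsplit(trimws(block), "\\s+")
    xyz <- t(vapply(parts, function(p) as.numeric(p[2:4]), numeric(3)))
    el <- vapply(parts, `[`, "", 1)
    frames[[length(frames) + 1]] <- xyz
    times <- c(times, if (is.na(tm)) length(times) else tm)
    i <- i + 2 + na
  }
  coords <- array(unlist(frames), c(nrow(frames[[1]]), 3, length(frames)))
  atoms <- data.frame(name = el, element = el,
                      role = ifelse(el == "O", "water_O",
                                    ifelse(el == "H", "water_H", "probe")),
                      mol_id = seq_along(el), resid = seq_along(el),
                      restype = "UNK")
  frame_set(coords, atoms, box, times = times)
}

#' Write a single frame as GRO
#'
#' Fixed-column GROMACS coordinate format; coordinates are Angstrom
#' internally and nanometres on file.
#'
#' @param fs a `frame_set`.
#' @param path output path.
#' @param frame frame index.
#' @export
write_gro <- function(fs, path, frame = 1) {
  x <- fs$coords[, , frame, drop = TRUE] / 10   # A -> nm
  n <- nrow(x)
  lines <- c(
    sprintf("synthetic frame, t= %.4f ns", fs$times[frame]),
    sprintf("%5d", n),
    sprintf("%5d%-5s%5s%5d%8.3f%8.3f%8.3f",
            fs$atoms$resid %% 100000, substr(fs$atoms$restype, 1, 5),
            substr(fs$atoms$name, 1, 5), seq_len(n) %% 100000,
            x[, 1], x[, 2], x[, 3]),
    sprintf("%10.5f%10.5f%10.5f", fs$box[1] / 10, fs$box[2] / 10, fs$box[3] / 10)
  )
  writeLines(lines, path)
  invisible(path)
}

#' Write / read a grain label map as a whitespace text matrix
#'
#' @param map integer label matrix.
#' @param path file path.
#' @export
write_label_map <- function(map, path) {
  utils::write.table(unclass(map), path, row.names = FALSE, col.names = FALSE)
  invisible(path)
}

#' @rdname write_label_map
#' @export
read_label_map <- function(path) {
  as.matrix(utils::read.table(path, header = FALSE))
}

#' Write a grain label map as PNG
#'
#' Labels are split across the red (high byte) and green (low byte) 8-bit
#' channels; [read_label_map_png()] inverts the encoding exactly for label
#' counts up to 65535.
#'
#' @param map integer label matrix.
#' @param path PNG path.
#' @export
write_label_map_png <- function(map, path) {
  m <- unclass(map)
  img <- array(0, c(nrow(m), ncol(m), 3))
  img[, , 1] <- (m %/% 256) / 255
  img[, , 2] <- (m %% 256) / 255
  png::writePNG(img, path)
  invisible(path)
}

#' @rdname write_label_map_png
#' @export
read_label_map_png <- function(path) {
  img <- png::readPNG(path)
  round(img[, , 1] * 255) * 256 + round(img[, , 2] * 255)
}

#' Write a per-frame label CSV
#'
#' Columns: frame, molecule_id, label, n_staggered, n_eclipsed.
#'
#' @param labels_list per-frame labels from [classify_frameset()].
#' @param path CSV path.
#' @export
write_labels_csv <- function(labels_list, path) {
  frames <- attr(labels_list, "frames") %||% seq_along(labels_list)
  df <- do.call(rbind, lapply(seq_along(labels_list), function(ii) {
    l <- labels_list[[ii]]
    data.frame(frame = frames[ii], molecule_id = seq_along(l$label),
               label = as.character(l$label),
               n_staggered = l$n_staggered, n_eclipsed = l$n_eclipsed)
  }))
  utils::write.csv(df, path, row.names = FALSE)
  invisible(path)
}

#' Per-frame phase count summary
#'
#' @param labels_list per-frame labels from [classify_frameset()].
#' @return data.frame of per-frame counts by phase label.
#' @export
phase_counts <- function(labels_list) {
  frames <- attr(labels_list, "frames") %||% seq_along(labels_list)
  do.call(rbind, lapply(seq_along(labels_list), function(ii) {
    tab <- table(labels_list[[ii]]$label)
    cbind(data.frame(frame = frames[ii]), as.data.frame(t(as.matrix(tab))))
  }))
}
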