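# STAR (RELION dialect) metadata reader/writer. Handles loop_ blocks with
# _rln column tags; both the flat 3.0-style particle table and the 3.1
# optics-group layout (data_optics + data_particles) are accepted.

#' Read a STAR file
#'
#' @param path file path.
#' @return named list of data.frames, one per `data_` block.
#' @export
read_star <- function(path) {
  lines <- readLines(path)
  lines <- trimws(lines)
  out <- list()
  i <- 1L
  nline <- length(lines)
  while (i <= nline) {
    if (startsWith(lines[i], "data_")) {
      block_name <- sub("^data_", "", lines[i])
      if (block_name == "") block_name <- "main"
      i <- i + 1L
      while (i <= nline && lines[i] != "loop_" && !startsWith(lines[i], "data_"))
        i <- i + 1L
      if (i > nline || startsWith(lines[i], "data_")) next
      i <- i + 1L  # past loop_
      cols <- character()
      while (i <= nline && startsWith(lines[i], "_")) {
        cols <- c(cols, sub("\\s+#\\d+$", "", sub("^_", "", lines[i])))
        i <- i + 1L
      }
      rows <- list()
      while (i <= nline && nzchar(lines[i]) && !startsWith(lines[i], "data_") &&
             !startsWith(lines[i], "#")) {
        rows[[length(rows) + 1L]] <- strsplit(lines[i], "\\s+")[[1]]
        i <- i + 1L
      }
      df <- as.data.frame(do.call(rbind, rows), stringsAsFactors = FALSE)
      names(df) <- cols
      for (cc in names(df)) {
        suppressWarnings(num <- as.numeric(df[[cc]]))
        if (!anyNA(num)) df[[cc]] <- num
      }
      out[[block_name]] <- df
    } else i <- i + 1L
  }
  out
}

#' Write a STAR file
#'
#' @param blocks named list of data.frames (block name without the `data_`
#'   prefix).
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_star <- function(blocks, path) {
  lines <- character()
  for (bn in names(blocks)) {
    df <- blocks[[bn]]
    lines <- c(lines, sprintf("data_%s", bn), "", "loop_",
               sprintf("_%s #%d", names(df), seq_along(df)))
    fmt <- vapply(df, function(col) {
      if (is.numeric(col)) sprintf("%.17g", col) else as.character(col)
    }, character(nrow(df)))
    if (nrow(df) == 1L) fmt <- matrix(fmt, nrow = 1)
    lines <- c(lines, apply(fmt, 1, paste, collapse = " "), "")
  }
  writeLines(lines, path)
  invisible(path)
}

star_need <- function(df, col) {
  if (!col %in% names(df))
    stop(sprintf("STAR file is missing the mandatory column %s", col))
  df[[col]]
}

star_opt <- function(df, col, default, warn = FALSE) {
  if (!col %in% names(df)) {
    if (warn) message(sprintf("STAR column %s missing; defaulting to %s",
                              col, format(default)))
    return(rep(default, nrow(df)))
  }
  df[[col]]
}

#' Read a particle set from STAR metadata and an MRC stack
#'
#' Understands the RELION particle columns (`rlnAngleRot`, `rlnAngleTilt`,
#' `rlnAnglePsi`, `rlnOriginXAngst`, `rlnOriginYAngst`, `rlnDefocusU`,
#' `rlnDefocusV`, `rlnDefocusAngle`, `rlnVoltage`,
#' `rlnSphericalAberration`, `rlnAmplitudeContrast`, `rlnImageName`);
#' missing shift columns default to zero with a message. Images are
#' resolved through the `index@stack` syntax relative to the STAR file's
#' directory; an optics block, when present, supplies per-group pixel size
#' via `rlnImagePixelSize`.
#'
#' @param star_path STAR file path.
#' @param pixel_size fallback pixel size when no optics block is present.
#' @return list of [particle_image()].
#' @export
read_particles <- function(star_path, pixel_size = NULL) {
  blocks <- read_star(star_path)
  df <- blocks$particles
  if (is.null(df)) df <- blocks$main
  if (is.null(df)) df <- blocks[[length(blocks)]]
  optics <- blocks$optics
  tilt <- star_need(df, "rlnAngleTilt")
  if (any(tilt < 0 | tilt > 180))
    stop("rlnAngleTilt outside [0, 180] degrees")
  rot <- star_need(df, "rlnAngleRot")
  psi <- star_need(df, "rlnAnglePsi")
  sx <- star_opt(df, "rlnOriginXAngst", 0, warn = TRUE)
  sy <- star_opt(df, "rlnOriginYAngst", 0, warn = TRUE)
  img_name <- star_need(df, "rlnImageName")
  px <- rep(if (is.null(pixel_size)) NA_real_ else pixel_size, nrow(df))
  if (!is.null(optics) && "rlnImagePixelSize" %in% names(optics)) {
    og <- star_opt(df, "rlnOpticsGroup", 1)
    px <- optics$rlnImagePixelSize[match(og, optics$rlnOpticsGroup)]
  }
  parts <- strsplit(img_name, "@", fixed = TRUE)
  stacks <- vapply(parts, `[`, character(1), 2)
  idx <- as.integer(vapply(parts, `[`, character(1), 1))
  base_dir <- dirname(star_path)
  cache <- new.env(parent = emptyenv())
  out <- vector("list", nrow(df))
  for (i in seq_len(nrow(df))) {
    sp <- stacks[i]
    if (is.null(cache[[sp]]))
      cache[[sp]] <- read_image_stack(file.path(base_dir, sp))
    stk <- cache[[sp]]
    psz <- if (is.na(px[i])) stk$pixel_size else px[i]
    out[[i]] <- particle_image(
      pixels = stk$images[[idx[i]]], pixel_size = psz,
      pose = particle_pose(rot[i], tilt[i], psi[i], sx[i], sy[i]),
      ctf = ctf_params(star_opt(df, "rlnDefocusU", 0)[i],
                       star_opt(df, "rlnDefocusV", 0)[i],
                       star_opt(df, "rlnDefocusAngle", 0)[i],
                       star_opt(df, "rlnVoltage", 300)[i],
                       star_opt(df, "rlnSphericalAberration", 2.7)[i],
                       star_opt(df, "rlnAmplitudeContrast", 0.1)[i]),
      id = i)
  }
  out
}

#' Write a particle set as STAR metadata plus an MRC stack
#'
#' @param particles list of [particle_image()].
#' @param star_path output STAR path.
#' @param stack_name stack file name, written next to the STAR file.
#' @return `star_path`, invisibly.
#' @export
write_particles <- function(particles, star_path,
                            stack_name = "particles.mrcs") {
  stopifnot(length(particles) >= 1)
  px <- particles[[1]]$pixel_size
  write_image_stack(lapply(particles, `[[`, "pixels"), px,
                    file.path(dirname(star_path), stack_name))
  getp <- function(f) vapply(particles, function(p) p$pose[[f]], numeric(1))
  getc <- function(f, default) vapply(particles, function(p) {
    if (is.null(p$ctf)) default else p$ctf[[f]]
  }, numeric(1))
  df <- data.frame(
    rlnImageName = sprintf("%06d@%s", seq_along(particles), stack_name),
    rlnAngleRot = getp("rot"), rlnAngleTilt = getp("tilt"),
    rlnAnglePsi = getp("psi"),
    rlnOriginXAngst = getp("sx"), rlnOriginYAngst = getp("sy"),
    rlnDefocusU = getc("defocus_u", 0), rlnDefocusV = getc("defocus_v", 0),
    rlnDefocusAngle = getc("defocus_angle", 0),
    rlnVoltage = getc("voltage", 300),
    rlnSphericalAberration = getc("cs", 2.7),
    rlnAmplitudeContrast = getc("amplitude_contrast", 0.1),
    rlnOpticsGroup = 1)
  optics <- data.frame(rlnOpticsGroup = 1, rlnImagePixelSize = px,
                       rlnVoltage = df$rlnVoltage[1],
                       rlnSphericalAberration = df$rlnSphericalAberration[1],
                       rlnAmplitudeContrast = df$rlnAmplitudeContrast[1])
  write_star(list(optics = optics, particles = df), star_path)
  invisible(star_path)
}
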