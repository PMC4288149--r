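# Trajectory, configuration and manifest I/O. Trajectories use a
# LAMMPS-dump-compatible text format (id type x y z qw qx qy qz); protocol
# and force-field configuration round-trip through YAML; manifests are
# JSON. Text outputs use locale-independent formatting with a fixed column
# order; coordinates are nm, times dual-stamped in tau_B and mapped ms.

ATOM_TYPES <- c(dna = 1L, octamer = 2L, nanoparticle = 3L)

format_num <- function(x) formatC(x, format = "g", digits = 17)

#' Write a trajectory (or single state) as a LAMMPS-style text dump
#'
#' Each frame carries `ITEM: TIMESTEP` (tau_B, and mapped ms on the same
#' line as a comment-free second field), box bounds, and per-atom lines
#' `id type x y z qw qx qy qz`. Types: 1 = DNA bead, 2 = octamer core,
#' 3 = nanoparticle.
#'
#' @param x a `bd_trajectory` or [system_state()].
#' @param path output file.
#' @param map [time_mapping()] for the ms stamp.
#' @export
write_trajectory <- function(x, path, map = time_mapping()) {
  states <- if (inherits(x, "bd_trajectory"))
    lapply(seq_along(x$times), function(i) traj_state(x, i))
  else list(x)
  con <- file(path, "w")
  on.exit(close(con))
  for (st in states) {
    a <- state_arrays(st)
    n <- nrow(a$pos) + nrow(a$cpos)
    allpos <- rbind(a$pos, a$cpos)
    allq <- rbind(a$quat, a$cquat)
    type <- c(rep(ATOM_TYPES[["dna"]], nrow(a$pos)),
              ifelse(a$ckind == 1L, ATOM_TYPES[["nanoparticle"]],
                     ATOM_TYPES[["octamer"]]))
    writeLines(c("ITEM: TIMESTEP",
                 paste(format_num(st$time), format_num(tau_to_ms(st$time, map))),
                 "ITEM: NUMBER OF ATOMS", as.character(n),
                 "ITEM: BOX BOUNDS ff ff ff",
                 vapply(1:3, function(k)
                   paste(format_num(min(allpos[, k]) - 5),
                         format_num(max(allpos[, k]) + 5)), "")), con)
    writeLines("ITEM: ATOMS id type x y z qw qx qy qz", con)
    writeLines(paste(seq_len(n), type,
                     format_num(allpos[, 1]), format_num(allpos[, 2]),
                     format_num(allpos[, 3]), format_num(allq[, 1]),
                     format_num(allq[, 2]), format_num(allq[, 3]),
                     format_num(allq[, 4])), con)
  }
  invisible(path)
}

#' Read a LAMMPS-style text dump
#'
#' Accepts dumps written by [write_trajectory()] as well as minimal
#' external dumps with only `id type x y z` columns (orientations then
#' default to identity). Parse errors report the offending line; a
#' truncated file errors naming the last complete frame.
#'
#' @param path dump file.
#' @return list of frames; each frame is a list with `time`, `atoms`
#'   (data.frame id, type, x, y, z, qw, qx, qy, qz).
#' @export
read_lammps_dump <- function(path) {
  ln <- readLines(path)
  frames <- list()
  i <- 1L
  nline <- length(ln)
  while (i <= nline) {
    if (!startsWith(ln[i], "ITEM: TIMESTEP"))
      stop(sprintf("parse error at line %d: expected ITEM: TIMESTEP", i),
           call. = FALSE)
    tparts <- strsplit(trimws(ln[i + 1]), "\\s+")[[1]]
    tm <- as.numeric(tparts[1])
    j <- i + 2L
    while (j <= nline && !startsWith(ln[j], "ITEM: NUMBER OF ATOMS"))
      j <- j + 1L
    if (j + 1L > nline)
      stop(sprintf(
        "parse error: truncated file after frame %d (line %d)",
        length(frames), nline), call. = FALSE)
    nat <- as.integer(trimws(ln[j + 1]))
    k <- j + 2L
    while (k <= nline && !startsWith(ln[k], "ITEM: ATOMS"))
      k <- k + 1L
    if (k > nline || k + nat > nline)
      stop(sprintf(
        "parse error: truncated file after frame %d (expected %d atoms)",
        length(frames), nat), call. = FALSE)
    hdr <- strsplit(sub("ITEM: ATOMS ?", "", ln[k]), "\\s+")[[1]]
    body <- ln[(k + 1):(k + nat)]
    vals <- utils::read.table(text = body, col.names = hdr)
    need <- c("id", "type", "x", "y", "z")
    if (!all(need %in% names(vals)))
      stop(sprintf("parse error at line %d: need columns id type x y z",
                   k), call. = FALSE)
    for (qc in c("qw", "qx", "qy", "qz"))
      if (!qc %in% names(vals)) vals[[qc]] <- if (qc == "qw") 1 else 0
    vals <- vals[order(vals$id),
                 c("id", "type", "x", "y", "z", "qw", "qx", "qy", "qz")]
    frames[[length(frames) + 1]] <- list(time = tm, atoms = vals)
    i <- k + nat + 1L
  }
  frames
}

#' Rebuild an analysis-ready system state from a dump frame
#'
#' With a `template` state (same composition) positions and orientations
#' are injected into it, preserving geometry, activation masks and chain
#' topology. Without one, a state is assembled from the frame alone:
#' type-1 atoms become a single linear DNA chain in file order, type-2/3
#' atoms become octamer/nanoparticle cores with the default geometry and
#' all sites active.
#'
#' @param frame one element of [read_lammps_dump()].
#' @param template optional [system_state()].
#' @param ff [ff_params()] for the default geometry.
#' @export
frame_to_state <- function(frame, template = NULL, ff = ff_params()) {
  at <- frame$atoms
  if (!is.null(template)) {
    nb <- sum(vapply(template$chains, n_beads, 1L))
    pos <- unname(as.matrix(at[at$type == ATOM_TYPES[["dna"]],
                               c("x", "y", "z")]))
    q <- unname(as.matrix(at[at$type == ATOM_TYPES[["dna"]],
                             c("qw", "qx", "qy", "qz")]))
    cp <- unname(as.matrix(at[at$type != ATOM_TYPES[["dna"]],
                              c("x", "y", "z")]))
    cq <- unname(as.matrix(at[at$type != ATOM_TYPES[["dna"]],
                              c("qw", "qx", "qy", "qz")]))
    stopifnot(nrow(pos) == nb, nrow(cp) == length(template$cores))
    return(state_update(template, pos, q, cp, cq, frame$time))
  }
  dna <- at[at$type == ATOM_TYPES[["dna"]], ]
  chain <- dna_chain(unname(as.matrix(dna[, c("x", "y", "z")])),
                     unname(as.matrix(dna[, c("qw", "qx", "qy", "qz")])))
  cores <- list()
  oct_geom <- core_geometry("octamer", path_radius = ff$path_radius,
                            path_pitch = ff$path_pitch,
                            body_diam = ff$core_diam)
  nano_geom <- core_geometry("nanoparticle", body_diam = ff$core_diam)
  prot <- at[at$type != ATOM_TYPES[["dna"]], ]
  for (i in seq_len(nrow(prot))) {
    g <- if (prot$type[i] == ATOM_TYPES[["nanoparticle"]]) nano_geom
         else oct_geom
    cores[[i]] <- core_particle(
      g, unname(unlist(prot[i, c("x", "y", "z")])),
      unname(unlist(prot[i, c("qw", "qx", "qy", "qz")])))
  }
  system_state(chain, cores, time = frame$time)
}

#' Read a trajectory file into states
#' @param path dump file.
#' @param template optional [system_state()] matching the composition.
#' @export
read_trajectory <- function(path, template = NULL) {
  lapply(read_lammps_dump(path), frame_to_state, template = template)
}

# ------------------------------------------------------------------- YAML --

#' Write / read a protocol (plus force-field overrides) as YAML
#' @param schedule a [make_protocol()] schedule.
#' @param path file.
#' @export
write_protocol_yaml <- function(schedule, path) {
  obj <- c(schedule[c("variant", "density", "placement", "topo", "scale",
                      "time_scale", "one_step")],
           schedule$inputs)
  yaml::write_yaml(obj, path, precision = 15)
  invisible(path)
}

#' @rdname write_protocol_yaml
#' @export
read_protocol_yaml <- function(path) {
  obj <- yaml::read_yaml(path)
  do.call(make_protocol, obj)
}

# ---------------------------------------------------------------- manifest --

# 31-bit FNV-1a variant over the serialized object: a stable,
# dependency-free config hash (kept below 2^31 for R's bitwXor)
config_hash <- function(obj) {
  raw <- serialize(obj, NULL, version = 2)
  h <- 21661366L
  for (b in as.integer(raw)) {
    h <- bitwXor(h, b)
    h <- as.integer((h * 16777619) %% 2147483647)
  }
  sprintf("%08x", h)
}

#' Write an experiment manifest as JSON
#' @param result an `experiment_result`.
#' @param path file.
#' @export
write_manifest <- function(result, path) {
  jsonlite::write_json(result$manifest, path, auto_unbox = TRUE,
                       digits = NA, pretty = TRUE)
  invisible(path)
}
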