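#' Sectional stem volume from mid-segment diameters (Hohenadl's formula)
#'
#' Computes stem volume from five equal-length stem segments whose diameters
#' were measured at the segment midpoints: the volume is the sum over segments
#' of mid-cross-sectional area times segment length,
#' \deqn{V = \sum_i \frac{\pi}{4} (d_i/100)^2 L_i,}
#' with \eqn{d_i} in cm and \eqn{L_i} in m.  This is the sectional form used
#' when a felled stem is cut into five pieces of equal length above the stump.
#'
#' @param segments a `stem_segments` object (see [stem_segments()]) or a
#'   data.frame with columns `length_m` and `mid_diameter_cm`.
#' @param tol relative tolerance for the equal-length check.
#' @return stem volume in m^3 (a positive scalar).
#' @examples
#' seg <- stem_segments(length_m = rep(2, 5), mid_diameter_cm = rep(10, 5))
#' hohenadl_volume(seg)  # 5 * (pi/4) * 0.1^2 * 2 = 0.0785398 m^3
#' @export
hohenadl_volume <- function(segments, tol = 1e-6) {
  segments <- as.data.frame(segments)
  n_seg <- nrow(segments)
  if (n_seg != 5L) {
    stop("Hohenadl's sectional formula needs exactly 5 stem segments, got ",
         n_seg, call. = FALSE)
  }
  L <- segments$length_m
  d <- segments$mid_diameter_cm
  if (any(!is.finite(L)) || any(!is.finite(d))) {
    stop("segment lengths and mid-diameters must be finite", call. = FALSE)
  }
  if (any(d <= 0)) stop("mid-diameters must be > 0", call. = FALSE)
  if (any(L <= 0)) stop("segment lengths must be > 0", call. = FALSE)
  if ((max(L) - min(L)) > tol * max(L)) {
    stop("segments must have equal length (relative tolerance ", tol, "); ",
         "got lengths ", paste(signif(L, 6), collapse = ", "), call. = FALSE)
  }
  sum((pi / 4) * (d / 100)^2 * L)
}

#' Stem segment records
#'
#' Builds a validated table of stem segments.  Diameters are mid-segment
#' diameters by convention (measured at the midpoint of each piece).  Disc
#' masses, when present, must satisfy `disc_dry_kg <= disc_fresh_kg` (a disc
#' cannot gain mass in the oven).
#'
#' @param length_m segment lengths (m, > 0).
#' @param mid_diameter_cm mid-segment diameters (cm, > 0).
#' @param fresh_mass_kg optional segment fresh masses (kg, >= 0).
#' @param disc_fresh_kg,disc_dry_kg optional disc fresh/oven-dry masses (kg).
#' @return a data.frame of class `stem_segments`.
#' @export
stem_segments <- function(length_m, mid_diameter_cm, fresh_mass_kg = NULL,
                          disc_fresh_kg = NULL, disc_dry_kg = NULL) {
  if (length(length_m) != length(mid_diameter_cm)) {
    stop("length_m and mid_diameter_cm must have equal length", call. = FALSE)
  }
  if (any(length_m <= 0)) stop("segment lengths must be > 0", call. = FALSE)
  if (any(mid_diameter_cm <= 0)) stop("mid-diameters must be > 0", call. = FALSE)
  out <- data.frame(length_m = as.numeric(length_m),
                    mid_diameter_cm = as.numeric(mid_diameter_cm))
  if (!is.null(fresh_mass_kg)) {
    if (any(fresh_mass_kg < 0)) stop("fresh masses must be >= 0", call. = FALSE)
    out$fresh_mass_kg <- as.numeric(fresh_mass_kg)
  }
  if (!is.null(disc_fresh_kg)) out$disc_fresh_kg <- as.numeric(disc_fresh_kg)
  if (!is.null(disc_dry_kg)) out$disc_dry_kg <- as.numeric(disc_dry_kg)
  if (!is.null(disc_fresh_kg) && !is.null(disc_dry_kg)) {
    bad <- which(disc_dry_kg > disc_fresh_kg)
    if (length(bad)) {
      stop("disc dry mass exceeds disc fresh mass for segment(s) ",
           paste(bad, collapse = ", "), call. = FALSE)
    }
  }
  class(out) <- c("stem_segments", "data.frame")
  out
}

#' Segment dry mass from disc moisture ratio
#'
#' Scales a segment's field fresh mass by the oven-dry to fresh mass ratio of
#' the disc sampled from it: `fresh_mass * disc_dry / disc_fresh`.  Vectorised.
#'
#' @param fresh_mass segment fresh mass (kg, >= 0).
#' @param disc_fresh disc fresh mass (kg, > 0).
#' @param disc_dry disc oven-dry mass (kg, with `0 <= disc_dry <= disc_fresh`).
#' @return dry mass in the units of `fresh_mass`.
#' @export
segment_dry_mass <- function(fresh_mass, disc_fresh, disc_dry) {
  if (any(fresh_mass < 0)) stop("fresh mass must be >= 0", call. = FALSE)
  if (any(disc_fresh <= 0)) stop("disc fresh mass must be > 0", call. = FALSE)
  if (any(disc_dry < 0)) stop("disc dry mass must be >= 0", call. = FALSE)
  if (any(disc_dry > disc_fresh)) {
    stop("disc dry mass exceeds disc fresh mass (impossible moisture ratio)",
         call. = FALSE)
  }
  fresh_mass * (disc_dry / disc_fresh)
}

#' Kilograms to megagrams
#'
#' All fitting downstream of I/O works in Mg so that BCEFs come out in
#' Mg m^-3; kilograms exist only at the file boundary.
#'
#' @param mass_kg mass in kg.
#' @return mass in Mg (tonnes).
#' @export
to_mg <- function(mass_kg) mass_kg / 1000

.components <- c("stem", "branches", "foliage", "crown", "agb")

#' Analysis-ready tree table
#'
#' Validates and completes a table of felled-tree records.  Component masses
#' are in Mg; `w_crown` and `w_agb` are always (re)derived from the primitive
#' components so the additivity identities `crown = branches + foliage` and
#' `agb = stem + crown` hold exactly.  Trees sampled leaf-off may carry
#' `w_foliage = 0`; a `foliage_absent` flag column is kept if supplied.
#'
#' @param df a data.frame with columns `species`, `volume_m3`, `w_stem`,
#'   `w_branches`, `w_foliage` (Mg), and optionally `dbh_cm`, `height_m`,
#'   `foliage_absent`.
#' @return the same data.frame with derived `w_crown`, `w_agb`, classed
#'   `tree_data`.
#' @export
tree_data <- function(df) {
  df <- as.data.frame(df)
  needed <- c("species", "volume_m3", "w_stem", "w_branches", "w_foliage")
  missing_cols <- setdiff(needed, names(df))
  if (length(missing_cols)) {
    stop("tree table lacks column(s): ", paste(missing_cols, collapse = ", "),
         call. = FALSE)
  }
  for (col in c("volume_m3", "w_stem", "w_branches", "w_foliage")) {
    if (!is.numeric(df[[col]])) {
      stop("column ", col, " must be numeric", call. = FALSE)
    }
  }
  if (any(df$volume_m3 <= 0)) {
    stop("stem volume must be > 0 for every record (rows ",
         paste(which(df$volume_m3 <= 0), collapse = ", "), ")", call. = FALSE)
  }
  for (col in c("w_stem", "w_branches", "w_foliage")) {
    if (any(df[[col]] < 0)) {
      stop("negative mass in column ", col, " (rows ",
           paste(which(df[[col]] < 0), collapse = ", "), ")", call. = FALSE)
    }
  }
  df$w_crown <- df$w_branches + df$w_foliage
  df$w_agb <- df$w_stem + df$w_crown
  class(df) <- unique(c("tree_data", class(df)))
  df
}

#' @export
print.tree_data <- function(x, ...) {
  cat("Tree biomass/volume table: ", nrow(x), " trees, ",
      length(unique(x$species)), " species\n", sep = "")
  cat("  volume [m^3]: ", signif(min(x$volume_m3), 4), "-",
      signif(max(x$volume_m3), 4),
      "; AGB [Mg]: ", signif(min(x$w_agb), 4), "-",
      signif(max(x$w_agb), 4), "\n", sep = "")
  NextMethod()
  invisible(x)
}

# default mapping from canonical fields to file columns (masses in kg on disk)
.default_column_map <- list(
  species = "species", dbh_cm = "dbh_cm", height_m = "height_m",
  volume_m3 = "volume_m3", w_stem = "stem_kg", w_branches = "branches_kg",
  w_foliage = "foliage_kg"
)

#' Read a delimited tree table
#'
#' Reads a delimited text file of tree-level measurements into an
#' analysis-ready [tree_data] table.  Masses are expected in kg on disk and
#' converted to Mg.  Rows with a missing stem volume fall back to
#' [hohenadl_volume()] applied to a long-format segment table keyed by tree
#' id; rows with neither volume nor segments are rejected and reported with
#' their row numbers in the `"rejected"` attribute.
#'
#' @param path path to the delimited file (header required).
#' @param column_map named list mapping canonical fields (`species`,
#'   `volume_m3`, `w_stem`, `w_branches`, `w_foliage`, optionally `dbh_cm`,
#'   `height_m`, `tree_id`) to file column names, or the path of a YAML file
#'   holding such a map.  Defaults cover the canonical header
#'   `species,dbh_cm,height_m,volume_m3,stem_kg,branches_kg,foliage_kg`.
#' @param sep field separator; `NULL` guesses between comma and tab.
#' @param mass_unit unit of the mass columns on disk, `"kg"` (default) or
#'   `"Mg"`.
#' @param segments_path optional path to a long-format segment file with
#'   columns `tree_id`, `length_m`, `mid_diameter_cm` (5 rows per tree).
#' @return a [tree_data] table; attribute `"rejected"` holds a data.frame of
#'   rejected row indices and reasons (empty when all rows load).
#' @export
read_tree_table <- function(path, column_map = NULL, sep = NULL,
                            mass_unit = c("kg", "Mg"), segments_path = NULL) {
  mass_unit <- match.arg(mass_unit)
  if (!file.exists(path)) stop("input file not found: ", path, call. = FALSE)
  cmap <- .resolve_column_map(column_map)
  if (is.null(sep)) {
    first <- readLines(path, n = 1L)
    sep <- if (grepl("\t", first)) "\t" else ","
  }
  raw <- utils::read.table(path, header = TRUE, sep = sep,
                           stringsAsFactors = FALSE, check.names = FALSE,
                           colClasses = "character")
  get_col <- function(field, required = TRUE) {
    file_col <- cmap[[field]]
    if (is.null(file_col) || !file_col %in% names(raw)) {
      if (required) {
        stop("column for field '", field, "' ('", file_col,
             "') not found in ", path, call. = FALSE)
      }
      return(NULL)
    }
    raw[[file_col]]
  }
  num_col <- function(field, required = TRUE) {
    v <- get_col(field, required)
    if (is.null(v)) return(NULL)
    v[v == ""] <- NA_character_
    out <- suppressWarnings(as.numeric(v))
    bad <- which(!is.na(v) & is.na(out))
    if (length(bad)) {
      stop("non-numeric value '", v[bad[1]], "' in column '", cmap[[field]],
           "', row ", bad[1], call. = FALSE)
    }
    out
  }
  species <- get_col("species")
  volume <- num_col("volume_m3", required = FALSE)
  if (is.null(volume)) volume <- rep(NA_real_, nrow(raw))
  masses <- lapply(c("w_stem", "w_branches", "w_foliage"), num_col)
  names(masses) <- c("w_stem", "w_branches", "w_foliage")
  for (col in names(masses)) {
    bad <- which(!is.na(masses[[col]]) & masses[[col]] < 0)
    if (length(bad)) {
      stop("negative mass in column '", cmap[[col]], "', row ", bad[1],
           call. = FALSE)
    }
  }
  bad_vol <- which(!is.na(volume) & volume <= 0)
  if (length(bad_vol)) {
    stop("non-positive stem volume in column '", cmap[["volume_m3"]],
         "', row ", bad_vol[1], " (rejected)", call. = FALSE)
  }
  # fall back to Hohenadl sectional volume where the volume cell is empty
  need_vol <- which(is.na(volume))
  if (length(need_vol)) {
    seg_tab <- NULL
    if (!is.null(segments_path)) {
      seg_tab <- utils::read.table(segments_path, header = TRUE, sep = sep,
                                   stringsAsFactors = FALSE)
    }
    tree_id <- get_col("tree_id", required = FALSE)
    for (i in need_vol) {
      segs <- NULL
      if (!is.null(seg_tab) && !is.null(tree_id)) {
        segs <- seg_tab[seg_tab$tree_id == tree_id[i], , drop = FALSE]
      }
      if (!is.null(segs) && nrow(segs) > 0) {
        volume[i] <- hohenadl_volume(segs)
      }
    }
  }
  rejected <- data.frame(row = integer(0), reason = character(0))
  still_missing <- which(is.na(volume))
  if (length(still_missing)) {
    rejected <- data.frame(
      row = still_missing,
      reason = "missing stem volume and no usable segment records"
    )
    warning(length(still_missing), " row(s) rejected: ",
            paste(still_missing, collapse = ", "),
            " (missing volume, no segments)", call. = FALSE)
  }
  keep <- setdiff(seq_len(nrow(raw)), still_missing)
  scale <- if (mass_unit == "kg") 1 / 1000 else 1
  df <- data.frame(
    species = species[keep],
    volume_m3 = volume[keep],
    w_stem = masses$w_stem[keep] * scale,
    w_branches = masses$w_branches[keep] * scale,
    w_foliage = masses$w_foliage[keep] * scale,
    stringsAsFactors = FALSE
  )
  dbh <- num_col("dbh_cm", required = FALSE)
  if (!is.null(dbh)) df$dbh_cm <- dbh[keep]
  ht <- num_col("height_m", required = FALSE)
  if (!is.null(ht)) df$height_m <- ht[keep]
  out <- tree_data(df)
  attr(out, "rejected") <- rejected
  out
}

.resolve_column_map <- function(column_map) {
  cmap <- .default_column_map
  if (is.null(column_map)) return(cmap)
  if (is.character(column_map) && length(column_map) == 1L) {
    column_map <- yaml::read_yaml(column_map)
    if (!is.null(column_map$column_map)) column_map <- column_map$column_map
  }
  if (!is.list(column_map)) {
    stop("column_map must be a named list or a YAML file path", call. = FALSE)
  }
  cmap[names(column_map)] <- column_map
  cmap
}

#' Write a tree table to CSV
#'
#' Writes the canonical wide layout (masses back in kg) at full numeric
#' precision, so a write/read cycle reproduces every field.
#'
#' @param data a [tree_data] table.
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_tree_table <- function(data, path) {
  stopifnot(inherits(data, "tree_data"))
  out <- data.frame(species = data$species)
  if (!is.null(data$dbh_cm)) out$dbh_cm <- data$dbh_cm
  if (!is.null(data$height_m)) out$height_m <- data$height_m
  out$volume_m3 <- data$volume_m3
  out$stem_kg <- data$w_stem * 1000
  out$branches_kg <- data$w_branches * 1000
  out$foliage_kg <- data$w_foliage * 1000
  utils::write.csv(format(out, digits = 17, trim = TRUE, scientific = FALSE),
                   path, row.names = FALSE, quote = TRUE)
  invisible(path)
}

#' Long-format (component, biomass, volume) pairs
#'
#' Reshapes a tree table to one row per tree x component, the unit every BCEF
#' fit consumes: species, component, dry biomass W (Mg), stem volume V (m^3).
#'
#' @param data a [tree_data] table.
#' @param components subset of `stem`, `branches`, `foliage`, `crown`, `agb`.
#' @return a long data.frame with columns `species`, `component`, `w_mg`,
#'   `v_m3`.
#' @export
as_wv_pairs <- function(data, components = .components) {
  stopifnot(inherits(data, "tree_data"))
  components <- match.arg(components, .components, several.ok = TRUE)
  do.call(rbind, lapply(components, function(comp) {
    data.frame(species = data$species, component = comp,
               w_mg = data[[paste0("w_", comp)]], v_m3 = data$volume_m3,
               stringsAsFactors = FALSE)
  }))
}
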