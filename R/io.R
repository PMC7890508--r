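# Delimited-text serialization of the world state and result tables.
# A world is a directory of CSV tables (comma, decimal point, UTF-8);
# writers are deterministic and round-trip through data.table's
# full-precision numeric formatting.

world_tables <- function() {
  c("countries.csv", "commodities.csv", "production.csv",
    "typical_diet.csv", "relations.csv", "composition.csv",
    "requirements.csv", "waste.csv")
}

fwrite_sorted <- function(df, path) {
  data.table::fwrite(df, path, quote = TRUE)
}

mat_long <- function(m, ids, codes, value = "value") {
  df <- data.frame(country = rep(ids, times = length(codes)),
                   commodity = rep(codes, each = length(ids)),
                   v = as.vector(m), stringsAsFactors = FALSE)
  names(df)[3] <- value
  df
}

long_mat <- function(df, ids, codes, value) {
  m <- matrix(0, length(ids), length(codes), dimnames = list(ids, codes))
  m[cbind(match(df$country, ids), match(df$commodity, codes))] <- df[[value]]
  m
}

#' Write a world to a directory of CSV tables
#'
#' @param world A `trade_world`.
#' @param dir Output directory (created if missing).
#' @return `dir`, invisibly.
#' @export
write_world <- function(world, dir) {
  if (!dir.exists(dir)) dir.create(dir, recursive = TRUE)
  ids <- world$countries$id
  codes <- world$commodities$code

  cs <- world$countries
  dm <- as.data.frame(world$demographics)
  names(dm) <- paste0("share_", names(dm))
  fwrite_sorted(cbind(cs, dm), file.path(dir, "countries.csv"))
  fwrite_sorted(world$commodities, file.path(dir, "commodities.csv"))

  b <- world$baseline
  prod <- data.frame(country = rep(ids, times = length(codes)),
                     commodity = rep(codes, each = length(ids)),
                     production = as.vector(b$production),
                     import = as.vector(b$import),
                     export = as.vector(b$export),
                     ds = as.vector(b$ds),
                     pct_food = as.vector(b$pct_food),
                     pct_loss = as.vector(b$pct_loss),
                     is_intermediary = as.vector(b$is_intermediary),
                     reexport = as.vector(b$reexport),
                     stringsAsFactors = FALSE)
  fwrite_sorted(prod, file.path(dir, "production.csv"))
  fwrite_sorted(mat_long(b$typical_diet, ids, codes, "tonnes"),
                file.path(dir, "typical_diet.csv"))

  r <- world$relations
  rel <- data.frame(from = rep(ids, times = length(ids)),
                    to = rep(ids, each = length(ids)),
                    distance_km = as.vector(r$distance),
                    historic_import = as.vector(r$historic_import),
                    historic_export = as.vector(r$historic_export),
                    emergent_import = as.vector(r$emergent_import),
                    emergent_export = as.vector(r$emergent_export),
                    stringsAsFactors = FALSE)
  fwrite_sorted(rel, file.path(dir, "relations.csv"))

  comp <- do.call(rbind, lapply(names(world$composition), function(variant) {
    m <- world$composition[[variant]]
    data.frame(variant = variant,
               commodity = rep(rownames(m), times = ncol(m)),
               nutrient = rep(colnames(m), each = nrow(m)),
               amount_per_tonne = as.vector(m), stringsAsFactors = FALSE)
  }))
  fwrite_sorted(comp, file.path(dir, "composition.csv"))

  rq <- world$requirements
  req <- data.frame(group = rep(rownames(rq$mean), times = ncol(rq$mean)),
                    nutrient = rep(colnames(rq$mean), each = nrow(rq$mean)),
                    value = as.vector(rq$mean), stringsAsFactors = FALSE)
  req$band_lower <- ifelse(req$nutrient == "fat",
                           rq$fat_lower[req$group], NA_real_)
  req$band_upper <- ifelse(req$nutrient == "fat",
                           rq$fat_upper[req$group], NA_real_)
  fwrite_sorted(req, file.path(dir, "requirements.csv"))

  w <- world$waste
  waste <- data.frame(region = rep(rownames(w), times = ncol(w)),
                      food_type = rep(colnames(w), each = nrow(w)),
                      fraction = as.vector(w), stringsAsFactors = FALSE)
  fwrite_sorted(waste, file.path(dir, "waste.csv"))
  invisible(dir)
}

read_table_checked <- function(dir, file, required) {
  path <- file.path(dir, file)
  if (!file.exists(path)) stop("schema error: missing table ", file)
  df <- as.data.frame(data.table::fread(path))
  missing <- setdiff(required, names(df))
  if (length(missing))
    stop("schema error: ", file, " lacks column(s) ",
         paste(missing, collapse = ", "))
  extra <- setdiff(names(df), c(required,
                                grep("^share_", names(df), value = TRUE)))
  if (length(extra))
    warning(file, ": ignoring stray column(s) ",
            paste(extra, collapse = ", "))
  df
}

#' Load a world from a directory of CSV tables
#'
#' Reads the tables written by [write_world()]; the loaded world must pass
#' [validate_world()] or loading fails with the violation list. Stray
#' columns are tolerated with a warning.
#'
#' @param dir Directory containing the world tables.
#' @return A `trade_world`.
#' @export
load_world <- function(dir) {
  cs <- read_table_checked(dir, "countries.csv",
                           c("id", "name", "lat", "lon", "region",
                             "income_class", "fortification", "population",
                             "gdp"))
  share_cols <- grep("^share_", names(cs), value = TRUE)
  if (!length(share_cols))
    stop("schema error: countries.csv lacks demographic share_ columns")
  demographics <- as.matrix(cs[share_cols])
  colnames(demographics) <- sub("^share_", "", share_cols)
  rownames(demographics) <- cs$id
  countries <- cs[c("id", "name", "lat", "lon", "region", "income_class",
                    "fortification", "population", "gdp")]

  commodities <- read_table_checked(dir, "commodities.csv",
                                    c("code", "name", "group",
                                      "edible_fraction", "refinable"))
  ids <- countries$id
  codes <- commodities$code

  prod <- read_table_checked(dir, "production.csv",
                             c("country", "commodity", "production",
                               "import", "export", "ds", "pct_food",
                               "pct_loss", "is_intermediary", "reexport"))
  diet <- read_table_checked(dir, "typical_diet.csv",
                             c("country", "commodity", "tonnes"))
  baseline <- list(
    production = long_mat(prod, ids, codes, "production"),
    import = long_mat(prod, ids, codes, "import"),
    export = long_mat(prod, ids, codes, "export"),
    ds = long_mat(prod, ids, codes, "ds"),
    pct_food = long_mat(prod, ids, codes, "pct_food"),
    pct_loss = long_mat(prod, ids, codes, "pct_loss"),
    typical_diet = long_mat(diet, ids, codes, "tonnes"),
    is_intermediary = long_mat(prod, ids, codes, "is_intermediary") > 0,
    reexport = long_mat(prod, ids, codes, "reexport"))

  rel <- read_table_checked(dir, "relations.csv",
                            c("from", "to", "distance_km",
                              "historic_import", "historic_export",
                              "emergent_import", "emergent_export"))
  rel_mat <- function(col) {
    m <- matrix(0, length(ids), length(ids), dimnames = list(ids, ids))
    m[cbind(match(rel$from, ids), match(rel$to, ids))] <- rel[[col]]
    m
  }
  relations <- list(distance = rel_mat("distance_km"),
                    historic_import = rel_mat("historic_import"),
                    historic_export = rel_mat("historic_export"),
                    emergent_import = rel_mat("emergent_import"),
                    emergent_export = rel_mat("emergent_export"))

  comp <- read_table_checked(dir, "composition.csv",
                             c("variant", "commodity", "nutrient",
                               "amount_per_tonne"))
  composition <- lapply(split(comp, comp$variant), function(d) {
    m <- matrix(0, length(codes), length(nutrients()),
                dimnames = list(codes, nutrients()))
    m[cbind(match(d$commodity, codes), match(d$nutrient, nutrients()))] <-
      d$amount_per_tonne
    m
  })

  req <- read_table_checked(dir, "requirements.csv",
                            c("group", "nutrient", "value", "band_lower",
                              "band_upper"))
  groups <- unique(req$group)
  mean_m <- matrix(0, length(groups), length(nutrients()),
                   dimnames = list(groups, nutrients()))
  mean_m[cbind(match(req$group, groups),
               match(req$nutrient, nutrients()))] <- req$value
  fat_rows <- req[req$nutrient == "fat", ]
  fat_lower <- stats::setNames(fat_rows$band_lower, fat_rows$group)[groups]
  fat_upper <- stats::setNames(fat_rows$band_upper, fat_rows$group)[groups]
  requirements <- list(mean = mean_m, fat_lower = fat_lower,
                       fat_upper = fat_upper)

  wt <- read_table_checked(dir, "waste.csv",
                           c("region", "food_type", "fraction"))
  regions <- unique(wt$region)
  types <- unique(wt$food_type)
  waste <- matrix(0, length(regions), length(types),
                  dimnames = list(regions, types))
  waste[cbind(match(wt$region, regions), match(wt$food_type, types))] <-
    wt$fraction

  world <- new_world(countries, demographics, commodities, composition,
                     baseline, relations, requirements, waste)
  v <- validate_world(world)
  if (length(v))
    stop("schema error: loaded world is invalid: ",
         paste(v, collapse = "; "))
  world
}

#' Write transactions as a delimited table
#'
#' @param transactions Transaction data frame.
#' @param path Output CSV path.
#' @return `path`, invisibly.
#' @export
write_transactions <- function(transactions, path) {
  data.table::fwrite(transactions, path, quote = TRUE)
  invisible(path)
}

#' Per-country nutrient intake table
#'
#' Wide layout: one row per country, one column per nutrient, per-capita
#' daily intake from the last simulated year.
#'
#' @param world A simulated `trade_world`.
#' @return Data frame with country id, population (millions) and one
#'   intake column per nutrient.
#' @export
intake_table <- function(world) {
  data.frame(country = world$countries$id,
             population_millions = world$countries$population / 1e6,
             world$current$nutrient_intake,
             stringsAsFactors = FALSE, row.names = NULL)
}

#' Sufficiency status across saturation scenarios
#'
#' Joins the sufficiency reports of several runs (e.g. the low/medium/high
#' saturation scenarios) into one table keyed by country and nutrient,
#' with one status column per scenario.
#'
#' @param reports Named list of sufficiency data frames (as produced by
#'   [step_year()] or the `reports` element of [run_horizon()]).
#' @return Data frame: country, nutrient, then one status column per
#'   scenario name.
#' @export
sufficiency_table <- function(reports) {
  stopifnot(length(reports) >= 1, !is.null(names(reports)))
  base <- reports[[1]][c("country", "nutrient")]
  out <- base
  for (nm in names(reports)) {
    r <- reports[[nm]]
    pos <- match(paste(base$country, base$nutrient),
                 paste(r$country, r$nutrient))
    out[[paste0("status_", nm)]] <- r$status[pos]
  }
  out
}
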