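# Independent day-by-day coverage simulation: walk the integer day grid,
# add supply at each event, consume one unit per non-hospital day, count
# hospital days as covered without consuming. The reference against which
# the interval-ledger CMA7 must agree exactly.
cma7_daygrid <- function(events, hosp = NULL, window_days) {
  in_hosp <- rep(FALSE, window_days)
  if (!is.null(hosp) && NROW(hosp)) {
    for (i in seq_len(NROW(hosp))) {
      a <- max(hosp$admission_day[i], 0)
      b <- min(hosp$discharge_day[i], window_days)
      if (b > a) in_hosp[(a + 1):b] <- TRUE
    }
  }
  add <- integer(window_days)
  for (i in seq_len(NROW(events))) {
    d <- events$day[i]
    if (d < window_days) add[d + 1] <- add[d + 1] + events$supply_days[i]
  }
  stock <- 0
  covered <- 0
  for (d in seq_len(window_days)) {
    stock <- stock + add[d]
    if (in_hosp[d]) {
      covered <- covered + 1
    } else if (stock > 0) {
      covered <- covered + 1
      stock <- stock - 1
    }
  }
  covered
}

# random treatment episode on the day grid (for property tests)
random_episode <- function() {
  k <- sample(1:8, 1)
  gaps <- sample(0:120, k - 1, replace = TRUE)
  events <- data.frame(day = cumsum(c(0L, gaps)),
                       supply_days = sample(c(30L, 90L), k, replace = TRUE))
  window <- max(events$day) + sample(1:150, 1)
  n_h <- sample(0:3, 1)
  hosp <- NULL
  if (n_h > 0) {
    admit <- sample(-10:(window - 1), n_h, replace = TRUE)
    hosp <- data.frame(admission_day = admit,
                       discharge_day = admit + sample(1:40, n_h, replace = TRUE))
  }
  list(events = events, hosp = hosp, window = window)
}

# dispensing fixture reproducing a two-arm switching pattern from given
# counts: each arm has `n` initiators of which `n_bg` switch brand<->generic
# (same molecule) and `n_mol` change molecule within follow-up
switch_count_fixture <- function(n_brand, bg_brand, mol_brand,
                                 n_generic, bg_generic, mol_generic) {
  one_arm <- function(n, n_bg, n_mol, prefix, brand0) {
    id <- sprintf("%s%05d", prefix, seq_len(n))
    index <- data.frame(patient_id = id,
                        index_date = as.Date("2010-06-15"),
                        molecule = "risedronic",
                        group = if (brand0) "brand" else "generic",
                        stringsAsFactors = FALSE)
    kind <- rep("none", n)
    if (n_bg > 0) kind[seq_len(n_bg)] <- "bg"
    if (n_mol > 0) kind[n_bg + seq_len(n_mol)] <- "mol"
    post <- data.frame(patient_id = id,
                       date = as.Date("2010-06-15") + 45L,
                       drug_class = "bisphosphonate",
                       molecule = ifelse(kind == "mol", "alendronic",
                                         "risedronic"),
                       brand = ifelse(kind == "bg", !brand0, brand0),
                       stringsAsFactors = FALSE)
    post <- post[kind != "none" | seq_len(n) %% 2 == 0, ]  # some never refill
    index_rows <- data.frame(patient_id = id,
                             date = as.Date("2010-06-15"),
                             drug_class = "bisphosphonate",
                             molecule = "risedronic",
                             brand = brand0,
                             stringsAsFactors = FALSE)
    list(index = index, dispensing = rbind(index_rows, post))
  }
  b <- one_arm(n_brand, bg_brand, mol_brand, "B", TRUE)
  g <- one_arm(n_generic, bg_generic, mol_generic, "G", FALSE)
  list(index_events = rbind(b$index, g$index),
       dispensing = rbind(b$dispensing, g$dispensing))
}

# episode table shaped like the study's printed persistence counts:
# `n_12m` persistent through follow-up, `n_died` deaths before 6 months,
# discontinuations split so that exactly `n_6m` patients pass 183 days
paper_episode_fixture <- function(group, n, n_6m, n_12m, n_died) {
  n_disc_late <- n_6m - n_12m
  n_disc_early <- n - n_12m - n_died - n_disc_late
  status <- c(rep("persistent", n_12m), rep("died", n_died),
              rep("discontinued", n_disc_late + n_disc_early))
  tt <- c(rep(NA_integer_, n_12m + n_died),
          rep(200L, n_disc_late), rep(100L, n_disc_early))
  end <- c(rep(365L, n_12m), rep(120L, n_died),
           rep(200L, n_disc_late), rep(100L, n_disc_early))
  data.table::data.table(
    patient_id = sprintf("%s%05d", substr(group, 1, 1), seq_len(n)),
    group = group, status = status,
    time_to_discontinuation = tt, end_day = end,
    censor_day = end, eligible = end >= 183L)
}
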