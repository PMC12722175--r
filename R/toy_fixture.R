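#' Hand-checkable toy cohort fixture
#'
#' A fixed, fully enumerated 10-person dataset whose derived quantities are
#' verified by hand in the test suite. Its contents (all dates ISO):
#'
#' * Persons 1-5 form the classic 5-subject competing-risk worked example:
#'   one same-day creatinine+ACR pair each on 2010-01-01, with follow-up
#'   times 1,2,3,4,5 days and events KRT, death, censored (emigration), KRT,
#'   censored (emigration). Their Aalen-Johansen curve has
#'   CIF_krt(5) = 1/5 + (3/5)(1/2) = 0.5, CIF_death(5) = (4/5)(1/4) = 0.2,
#'   S(5) = 0.3.
#' * Person 6 has creatinine on 2010-01-01 and albuminuria 400 days later
#'   (2011-02-05): outside the 365-day pairing window, so no record.
#' * Person 7 (index 2010-06-01, ACR 350 mg/g) has four distinct
#'   antihypertensive classes dispensed on 2010-04-15 (well inside the
#'   183-day lookback) plus a repeat fill of one class: refractory
#'   hypertension positive (distinct count 4).
#' * Person 8's first record (2010-01-01, creatinine 60 umol/L, age 40)
#'   has eGFR about 96.8 >= 60: the person is excluded even though their
#'   second record (2011-06-01, creatinine 130) has eGFR < 60.
#' * Person 9 pairs a creatinine (2010-03-01) with a dipstick test ten days
#'   later (2010-03-11, category 2+): index is the later date.
#' * Person 10 has a same-day PCR reported in mg/mmol (unit conversion and
#'   PCR-to-ACR mapping both exercised).
#' * Person 2 also has a single beta-blocker fill 31 days before index
#'   (distinct antihypertensive count 1).
#'
#' The administrative end of data collection for the fixture is 2019-12-31
#' (returned as `admin_end`).
#'
#' @return list with `persons`, `lab_tests`, `dispensations`, `outcomes`,
#'   `admin_end`
#' @export
make_toy_fixture <- function() {
  persons <- data.frame(
    person_id = 1:10,
    sex = c("female", "male", "female", "male", "female", "male", "female",
            "female", "male", "female"),
    birth_date = as.Date(c("1935-01-01", "1930-01-01", "1940-01-01",
                           "1942-01-01", "1928-01-01", "1933-01-01",
                           "1937-06-01", "1970-01-01", "1935-03-01",
                           "1931-04-01")),
    diabetes = c(FALSE, TRUE, FALSE, FALSE, FALSE, FALSE, TRUE, FALSE,
                 FALSE, FALSE),
    hypertension = c(TRUE, TRUE, FALSE, TRUE, FALSE, FALSE, TRUE, FALSE,
                     TRUE, TRUE))
  lab <- function(pid, date, analyte, value = NA_real_, unit = NA_character_,
                  category = NA_character_) {
    data.frame(person_id = pid, date = as.Date(date), analyte = analyte,
               value = value, unit = unit, category = category)
  }
  lab_tests <- rbind(
    lab(1, "2010-01-01", "creatinine", 120, "umol/L"),
    lab(1, "2010-01-01", "acr", 100, "mg/g"),
    lab(2, "2010-01-01", "creatinine", 120, "umol/L"),
    lab(2, "2010-01-01", "acr", 60, "mg/g"),
    lab(3, "2010-01-01", "creatinine", 120, "umol/L"),
    lab(3, "2010-01-01", "acr", 40, "mg/g"),
    lab(4, "2010-01-01", "creatinine", 120, "umol/L"),
    lab(4, "2010-01-01", "acr", 250, "mg/g"),
    lab(5, "2010-01-01", "creatinine", 120, "umol/L"),
    lab(5, "2010-01-01", "acr", 30, "mg/g"),
    lab(6, "2010-01-01", "creatinine", 130, "umol/L"),
    lab(6, "2011-02-05", "acr", 50, "mg/g"),
    lab(7, "2010-06-01", "creatinine", 125, "umol/L"),
    lab(7, "2010-06-01", "acr", 350, "mg/g"),
    lab(8, "2010-01-01", "creatinine", 60, "umol/L"),
    lab(8, "2010-01-01", "acr", 20, "mg/g"),
    lab(8, "2011-06-01", "creatinine", 130, "umol/L"),
    lab(8, "2011-06-01", "acr", 25, "mg/g"),
    lab(9, "2010-03-01", "creatinine", 118, "umol/L"),
    lab(9, "2010-03-11", "dipstick", category = "2+"),
    lab(10, "2010-04-01", "creatinine", 122, "umol/L"),
    lab(10, "2010-04-01", "pcr", 20, "mg/mmol"))
  disp <- function(pid, date, cls) {
    data.frame(person_id = pid, date = as.Date(date), drug_class = cls)
  }
  dispensations <- rbind(
    disp(2, "2009-12-01", "beta_blocker"),
    disp(7, "2010-04-15", "acei"),
    disp(7, "2010-04-15", "arb"),
    disp(7, "2010-04-15", "ccb"),
    disp(7, "2010-04-15", "thiazide"),
    disp(7, "2010-05-20", "acei"))
  outcomes <- data.frame(
    person_id = 1:10,
    krt_date = as.Date(c("2010-01-02", NA, NA, "2010-01-05", NA, NA, NA, NA,
                         NA, NA)),
    death_date = as.Date(c(NA, "2010-01-03", NA, NA, NA, NA, NA, NA, NA, NA)),
    emigration_date = as.Date(c(NA, NA, "2010-01-04", NA, "2010-01-06", NA,
                                NA, NA, NA, "2015-01-01")))
  list(persons = persons, lab_tests = lab_tests,
       dispensations = dispensations, outcomes = outcomes,
       admin_end = as.Date("2019-12-31"))
}
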