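#' @name lexicons
#' @title Surface-form lexicons for the synthetic corpus generator
#' @description
#' Every fine-grained PHI type carries pools of surface forms in up to
#' three script classes: `en` (contains Latin letters), `zh` (contains Han
#' characters) and `num` (digits/punctuation only).  Each pool is split
#' into three disjoint slices: `shared` surfaces may appear in both
#' splits, `heldout` surfaces are reserved for test-only sampling (they
#' realize the out-of-vocabulary rate), and `surrogate` surfaces are used
#' exclusively by [resynthesize()].
#'
#' The default lexicon is constructed so that, before any deliberate
#' ambiguity is injected, every token text occupies exactly one
#' (BILOU position, fine type) role across the whole lexicon.  A corpus
#' drawn from it with `ambiguity_rate = 0` therefore never assigns two
#' different gold labels to one token type, the regime in which a
#' most-frequent-tag dictionary can reach perfect recall.
NULL

# cross two slices of name components into "First Last" surfaces
cross_names <- function(first, last) {
  as.vector(outer(first, last, paste))
}

cross_zh_names <- function(surnames, givens) {
  as.vector(outer(surnames, givens, paste0))
}

lex_rows <- function(fine_type, surfaces, script, pattern, slice) {
  if (!length(surfaces)) return(NULL)
  data.frame(fine_type = fine_type, surface = surfaces, script = script,
             pattern = pattern, slice = slice, stringsAsFactors = FALSE)
}

pool3 <- function(fine_type, script, pattern, shared, heldout, surrogate) {
  rbind(lex_rows(fine_type, shared, script, pattern, "shared"),
        lex_rows(fine_type, heldout, script, pattern, "heldout"),
        lex_rows(fine_type, surrogate, script, pattern, "surrogate"))
}

iso_dates <- function(years) {
  months <- sprintf("%02d", 1:12)
  days <- c("14", "17", "21", "25", "28")
  as.vector(outer(as.vector(outer(years, months,
                                  function(y, m) paste(y, m, sep = "/"))),
                  days, function(ym, d) paste(ym, d, sep = "/")))
}

#' Build the default generator lexicon
#'
#' @param ambiguity_rate Fraction of non-numeric shared lexicon entries
#'   duplicated under a second fine type, creating genuinely ambiguous
#'   surfaces (e.g. a place name that is also a hospital name).
#' @param seed Integer seed controlling which entries are aliased.
#' @return A data.frame with columns `fine_type`, `surface`, `script`,
#'   `pattern`, `slice`.
#' @export
cm_lexicons <- function(ambiguity_rate = 0.05, seed = 1L) {
  stopifnot(ambiguity_rate >= 0, ambiguity_rate <= 1)
  lx <- rbind(
    # --- Date: slashed numeric, ROC "mk" transliteration, Chinese-numeral
    pool3("Date", "num", "iso",
          iso_dates(2138:2143), iso_dates(2151:2156), iso_dates(2161:2166)),
    pool3("Date", "en", "mk",
          paste0("mk", 131:140), paste0("mk", 151:158), paste0("mk", 161:168)),
    pool3("Date", "zh", "zh",
          c("三月六日", "五月九日", "七月八日", "中秋節"),
          c("端午節", "十月二日"),
          c("四月一日", "重陽節")),
    # --- Age: bare two-digit ages (days/months/rooms use other ranges)
    pool3("Age", "num", "num",
          as.character(31:42), as.character(65:85), as.character(86:99)),
    # --- Names: First/Last crossed within slices; Chinese surname+given
    pool3("Patient", "en", "en",
          cross_names(c("Alice", "Brenda"), c("Womack", "Pruitt")),
          cross_names(c("Felicia", "Gordon"), c("Quimby", "Rafferty")),
          cross_names(c("Harriet", "Irving"), c("Sexton", "Thornbury"))),
    pool3("Patient", "zh", "zh",
          cross_zh_names(c("陳", "林"), c("偉倫", "秀蘭")),
          cross_zh_names(c("許", "鄭"),
                         c("玉瑜", "文彬")),
          cross_zh_names(c("賴", "潘"),
                         c("冠廷", "芸萱"))),
    pool3("Person", "en", "en",
          cross_names(c("Jared", "Kelsey"), c("Vickers", "Winslow")),
          cross_names(c("Opal", "Preston"), c("Bickford", "Cavanaugh")),
          cross_names(c("Quincy", "Rosalind"), c("Dunmore", "Ellsworth"))),
    pool3("Person", "zh", "zh",
          cross_zh_names(c("吳", "郭"), c("淑惠", "志豪")),
          cross_zh_names(c("謝", "曾"),
                         c("建甫", "麗君")),
          cross_zh_names(c("邱", "廖"),
                         c("宗翰", "佩珊"))),
    pool3("Doctor", "en", "en",
          cross_names(c("Samuel", "Tanya", "Ulric", "Vera", "Wendell"),
                      c("Beaumont", "Crawford", "Delgado", "Eastwood",
                        "Farnsworth")),
          cross_names(c("Xavier", "Yolanda"), c("Galloway", "Hathaway")),
          cross_names(c("Zachary", "Ambrose"), c("Ingram", "Jarvis"))),
    pool3("Doctor", "zh", "zh",
          cross_zh_names(c("張", "王", "李"),
                         c("家明", "世勳", "心怡")),
          cross_zh_names(c("劉", "莊"),
                         c("凱傑", "若琳")),
          cross_zh_names(c("蘇", "游"),
                         c("士賢", "孟潔"))),
    # --- Location fine types
    pool3("Named location", "en", "en",
          c("Alishan", "Taroko", "Kenting", "Yangmingshan", "Sizihwan"),
          c("Maokong", "Cingjing"), c("Lalashan", "Liyutan")),
    pool3("Named location", "zh", "zh",
          c("阿里山", "墾丁", "太魯閣"),
          c("貓空", "鯉魚潭"),
          c("清境", "合歡山")),
    pool3("Nationality", "en", "en",
          c("Japanese", "Canadian", "Filipino", "Vietnamese", "Indonesian"),
          c("Thai", "Burmese"), c("Malaysian", "Nepali")),
    pool3("Region", "en", "en",
          c("Midtown", "Uptown", "Lakeside", "Riverside", "Hillside"),
          c("Seaside", "Parkside"), c("Downtown", "Westside")),
    pool3("Country", "en", "en",
          c("Japan", "Canada", "France", "Germany", "Brazil"),
          c("Norway", "Egypt"), c("Peru", "Chile")),
    pool3("Country", "zh", "zh",
          c("美國", "英國", "法國"),
          c("泰國", "韓國"),
          c("德國", "緬甸")),
    pool3("City", "en", "en",
          c("Taipei", "Kaohsiung", "Tainan"),
          c("Hualien", "Yilan"), c("Chiayi", "Pingtung")),
    pool3("City", "zh", "zh",
          c("台北", "高雄", "嘉義"),
          c("花蓮", "基隆"),
          c("苗栗", "彰化")),
    pool3("Hospital", "en", "en",
          paste(c("Mercy", "Harbor", "Summit", "Unity", "Beacon"),
                "Hospital"),
          paste(c("Crescent", "Pinnacle"), "Hospital"),
          paste(c("Meadow", "Keystone"), "Hospital")),
    pool3("Hospital", "zh", "zh",
          c("仁愛醫院", "和平醫院",
            "長庚醫院", "療養院"),
          c("榮總", "慈濟醫院"),
          c("培元醫院")),
    pool3("Hospital", "num", "num",   # army-style numeric hospital names
          as.character(701:706), as.character(731:740),
          as.character(751:760)),
    pool3("Department", "en", "en",
          c("Cardiology", "Neurology", "Psychiatry", "Oncology",
            "Dermatology"),
          c("Urology", "Nephrology"), c("Radiology", "Hematology")),
    pool3("Department", "zh", "zh",
          c("內科", "外科", "兒科", "眼科"),
          c("牙科", "骨科"),
          c("皮膚科", "復健科")),
    pool3("Room", "en", "en",
          paste("Ward", c("A", "B", "C", "D", "E")),
          paste("Ward", c("K", "M")), paste("Ward", c("P", "R"))),
    pool3("Room", "num", "num",
          as.character(301:312), as.character(401:430),
          as.character(501:530)),
    pool3("Number", "num", "num",
          as.character(801:808), as.character(841:855),
          as.character(871:885)),
    pool3("School", "en", "en",
          c("NKUST", "NTHU", "NCKU"),
          c("NTUT", "NCUE"), c("NUTC", "NPTU")),
    pool3("School", "zh", "zh",
          c("育才大學", "弘光大學",
            "靜修大學"),
          c("崇右大學", "致遠大學"),
          c("開南大學", "實踐大學")),
    pool3("Generic location", "en", "en",
          paste(c("Green", "Rose", "Oak", "Cedar", "Maple"), "Park"),
          paste(c("Elm", "Ivy"), "Park"), paste(c("Fern", "Birch"), "Park")),
    pool3("Generic location", "zh", "zh",
          c("河濱公園", "碧湖公園",
            "雙連公園"),
          c("虎頭公園", "晴川公園"),
          c("福祿公園")),
    pool3("Market", "en", "en",
          paste(c("Jade", "Flower", "Silk", "Amber", "Pearl"), "Market"),
          paste(c("Coral", "Ivory"), "Market"),
          paste(c("Onyx", "Topaz"), "Market")),
    pool3("Market", "zh", "zh",
          c("東門夜市", "廟口夜市",
            "饒曲夜市"),
          c("樂華夜市"), c("瑞豐夜市")),
    # --- Profession
    pool3("Profession", "en", "en",
          c("carpenter", "plumber", "electrician", "accountant", "florist"),
          c("welder", "barista"), c("tailor", "machinist")),
    pool3("Profession", "zh", "zh",
          c("會計師", "理容師", "廚師"),
          c("律師", "攝影師"),
          c("藥師", "測量師")),
    # --- IDs
    pool3("ID number", "num", "num",
          sprintf("%08d", 23456701 + 13 * (0:11)),
          sprintf("%08d", 45600001 + 17 * (0:19)),
          sprintf("%08d", 78900001 + 19 * (0:19))),
    pool3("Medical record", "en", "en",
          paste0("MR", 50000 + 37 * (0:7)),
          paste0("MR", 70000 + 41 * (0:14)),
          paste0("MR", 90000 + 43 * (0:14))),
    pool3("Medical record", "zh", "zh",
          paste0("病歷", 60000 + 37 * (0:7)),
          paste0("病歷", 80000 + 41 * (0:14)),
          paste0("病歷", 40000 + 43 * (0:14)))
  )
  rownames(lx) <- NULL
  if (ambiguity_rate > 0) {
    lx <- inject_ambiguity(lx, ambiguity_rate, seed)
  }
  lx
}

# Duplicate a fraction of non-numeric shared entries under a second fine
# type of the same script (preferring the same coarse type), so that some
# surfaces legitimately belong to >= 2 fine types.
inject_ambiguity <- function(lx, rate, seed) {
  schema <- phi_schema()
  cand <- which(lx$slice == "shared" & lx$script %in% c("en", "zh"))
  n_alias <- floor(rate * length(cand))
  if (n_alias < 1) return(lx)
  rng <- local_rng(seed + 77003L)
  pick <- cand[rng$sample_int(length(cand), n_alias)]
  extra <- lapply(pick, function(i) {
    ft <- lx$fine_type[i]
    sc <- lx$script[i]
    same_script <- setdiff(unique(lx$fine_type[lx$script == sc]), ft)
    if (!length(same_script)) return(NULL)
    same_coarse <- same_script[coarse_of(same_script, schema) ==
                                 coarse_of(ft, schema)]
    pool <- if (length(same_coarse)) same_coarse else same_script
    partner <- pool[rng$sample_int(length(pool), 1)]
    data.frame(fine_type = partner, surface = lx$surface[i], script = sc,
               pattern = lx$pattern[i], slice = "shared",
               stringsAsFactors = FALSE)
  })
  extra <- do.call(rbind, extra)
  out <- rbind(lx, extra)
  rownames(out) <- NULL
  out
}

# Token -> role audit used by tests and by the generator's sanity check:
# returns a data.frame of tokens that occupy more than one
# (position, fine_type) role in the lexicon plus filler inventories.
lexicon_role_conflicts <- function(lx = cm_lexicons(ambiguity_rate = 0)) {
  roles <- list()
  add_role <- function(token, role) {
    roles[[token]] <<- union(roles[[token]], role)
  }
  for (i in seq_len(nrow(lx))) {
    toks <- tokenize_mixed(lx$surface[i])$text
    labs <- encode_bilou(tokenize_mixed(lx$surface[i]),
                         data.frame(start = 0L,
                                    end = nchar(lx$surface[i]),
                                    fine_type = lx$fine_type[i]))
    for (j in seq_along(toks)) add_role(toks[j], labs[j])
  }
  for (w in unlist(filler_inventory())) {
    for (t in tokenize_mixed(w)$text) add_role(t, "O")
  }
  bad <- names(roles)[vapply(roles, length, integer(1)) > 1]
  data.frame(token = bad,
             roles = vapply(roles[bad], paste, character(1), collapse = ","),
             stringsAsFactors = FALSE)
}

filler_inventory <- function() {
  list(
    en = c("the", "patient", "was", "admitted", "due", "to", "for",
           "evaluation", "and", "treatment", "with", "stable", "mood",
           "denied", "ideation", "followed", "up", "at", "clinic", "since",
           "noted", "plan", "continue", "medication", "on", "discharge",
           "visit", "arranged", "regular", "daily", "improved", "he", "she",
           "reported", "sleep", "appetite", "fair", "of", "condition", "Dr"),
    zh = c("情緒穩定", "睡眠改善", "食欲正常", "按時返診",
           "持續追蹤", "狀況好轉", "無異", "親屬陪同",
           "規則作息", "回診安排"),
    punct = c(".", ",", ":", ";", "(", ")"),
    num = c(as.character(0:9), "~", ">", "+", "*", "=", "%")
  )
}
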