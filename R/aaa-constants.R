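# Shared enums and constants (loaded first by collation order).

EARS <- c("left", "right")
AGE_BANDS <- c("child", "adult")
MODES <- c("otoscopy", "tympanometry", "audiometry")
OTO_CATEGORIES <- c(
  "clear_normal", "occluding_cerumen", "erythema", "effusion",
  "perforation", "pe_tube", "foreign_body", "other"
)
NOTE_SLOTS <- c(
  "otoscopy_left", "otoscopy_right",
  "tympanometry_left", "tympanometry_right",
  "audiometry_left", "audiometry_right"
)
RECOMMENDATIONS <- c("pass", "refer_audiologist", "refer_physician",
                     "refer_both")
GRADE_ITEMS <- c(NOTE_SLOTS, "final_recommendation")
EVENT_KINDS <- c("select_mode", "select_ear", "set_level", "set_frequency",
                 "oto_exam", "tymp_exam", "tone_presented", "notes_saved")
ACTION_KINDS <- c("select_mode", "select_ear", "set_level", "set_frequency",
                  "oto_exam", "tymp_exam", "present_tone", "save_notes",
                  "end_session")
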