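# Default self-report pattern grammar.
#
# Templates are regex skeletons. Placeholders: {identity} (identity term),
# {person} (singular person term), {people} (plural person term), {mod}
# (zero to two intervening modifier words, e.g. "gay trans man"). Spaces
# match any whitespace run; straight apostrophes also match curly ones;
# matching is case-insensitive with word-boundary semantics. Note {mod}
# must directly abut the following placeholder ("{mod}{person}").
#
# Tweet templates require a first-person anchor; profile templates accept
# a bare identity+person collocation because profile text is
# self-descriptive by convention. Edit a copy of this file and pass it to
# compile_pattern_set(default_pattern_config("my_patterns.yaml")) to use a
# custom inventory.

identity_terms:
  - gay
  - bi
  - bisexual
  - homosexual
  - msm
  - men who have sex with men

person_terms:
  - man
  - guy
  - male
  - dude
  - boy

people_terms:
  - men
  - guys
  - males
  - dudes
  - boys
  - people

tweet_templates:
  first_person_identity: "(?:i'm|i am|im) an? {mod}{identity} {mod}{person}"
  as_a: "as an? {mod}{identity} {mod}{person}"
  like_me: "{identity} {mod}{people} like me"
  being_a: "being an? {mod}{identity} {mod}{person}"
  first_person_msm: "(?:i'm|i am|im) msm"

profile_templates:
  identity_person: "{identity} {mod}{person}"
  identity_people: "{identity} {mod}{people}"
  msm_profile: "msm"
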