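# The 10 US states with the highest numbers of new HIV diagnoses
# (reconstructed from public CDC HIV surveillance reports, diagnoses year
# 2019). Editable: replace with the list for another surveillance year.
kind,name,state
state,California,CA
state,Texas,TX
state,Florida,FL
state,Georgia,GA
state,New York,NY
state,Illinois,IL
state,North Carolina,NC
state,Louisiana,LA
state,Maryland,MD
state,Ohio,OH
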