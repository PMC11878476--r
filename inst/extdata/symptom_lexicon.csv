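surface,canonical,category
memory loss,memory_loss,symptom
memory losses,memory_loss,symptom
loss of memory,memory_loss,symptom
memory impairment,memory_loss,symptom
memory deficit,memory_loss,symptom
poor memory,memory_loss,symptom
worsening memory,memory_loss,symptom
memory problems,memory_loss,symptom
memory difficulty,memory_loss,symptom
trouble remembering,memory_loss,symptom
difficulty remembering,memory_loss,symptom
not recalling,memory_loss,symptom
cannot recall,memory_loss,symptom
forgetfulness,forgetfulness,symptom
forgetful,forgetfulness,symptom
forgetting,forgetfulness,symptom
forgetting things,forgetfulness,symptom
forgets names,forgetfulness,symptom
short-term memory loss,short_term_memory_deficit,symptom
short term memory loss,short_term_memory_deficit,symptom
short-term memory deficit,short_term_memory_deficit,symptom
short term memory deficit,short_term_memory_deficit,symptom
poor short-term memory,short_term_memory_deficit,symptom
stml,short_term_memory_deficit,symptom
confusion,confusion,symptom
confused,confusion,symptom
episodes of confusion,confusion,symptom
blackout,confusion,symptom
blackouts,confusion,symptom
cognitive impairment,cognitive_impairment,symptom
cognition impairment,cognitive_impairment,symptom
cognitive decline,cognitive_impairment,symptom
cognitive deficits,cognitive_impairment,symptom
declining cognition,cognitive_impairment,symptom
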