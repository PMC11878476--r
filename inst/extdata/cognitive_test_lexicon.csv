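surface,canonical,category
mmse,mmse,cognitive_test
mini mental state exam,mmse,cognitive_test
mini-mental state examination,mmse,cognitive_test
slums,slums,cognitive_test
moca,moca,cognitive_test
montreal cognitive assessment,moca,cognitive_test
mini-cog,mini_cog,cognitive_test
mini cog,mini_cog,cognitive_test
clock drawing,clock_drawing,cognitive_test
clock drawing test,clock_drawing,cognitive_test
trail making,trail_making,cognitive_test
trail making test,trail_making,cognitive_test
boston naming,boston_naming,cognitive_test
boston naming test,boston_naming,cognitive_test
wisconsin card sorting,wisconsin_card_sorting,cognitive_test
wisconsin card sorting test,wisconsin_card_sorting,cognitive_test
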