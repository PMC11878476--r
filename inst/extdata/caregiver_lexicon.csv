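surface,canonical,category
husband,husband,caregiver
hubby,husband,caregiver
spouse (husband),husband,caregiver
wife,wife,caregiver
spouse (wife),wife,caregiver
daughter,daughter,caregiver
dtr,daughter,caregiver
dghtr,daughter,caregiver
son,son,caregiver
son-in-law,son_in_law,caregiver
son in law,son_in_law,caregiver
daughter-in-law,daughter_in_law,caregiver
daughter in law,daughter_in_law,caregiver
dtr-in-law,daughter_in_law,caregiver
grandson,grandson,caregiver
granddaughter,granddaughter,caregiver
grand-daughter,granddaughter,caregiver
nephew,nephew,caregiver
niece,niece,caregiver
cousin,cousin,caregiver
brother,brother,caregiver
bro,brother,caregiver
sister,sister,caregiver
sis,sister,caregiver
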