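column,type,values,description
patient_id,character,,Opaque patient identifier; unique within the registry
hospital_id,character,,Opaque hospital identifier
age_years,integer,>= 0,Completed years of age at surgery
sex,category,female|male,Patient sex; empty = missing
asa_class,category,asa12|asa34,ASA physical status grouped 1-2 vs 3-4
dementia,category,no|yes|unknown,Cognitive status; 'unknown' is a recorded level distinct from missing
katz6_adl,integer,0-6,Katz Index of Independence in ADL; higher = more dependent
living_situation,category,independent|institutionalized,Pre-fracture living situation
fracture_type,category,fn_nondisplaced|fn_displaced|a1|a2|a3|subtrochanteric,Fracture classification
pathologic_fracture,boolean,true|false,Pathologic fracture (exclusion criterion)
periprosthetic_fracture,boolean,true|false,Periprosthetic fracture (exclusion criterion)
treatment,category,osteosynthesis|prosthesis,Type of operation
ed_arrival,timestamp,ISO-8601,Arrival at the emergency department (local clock time)
surgery_start,timestamp,ISO-8601,Start of surgery
discharge,timestamp,ISO-8601,Hospital discharge; empty = missing
malnutrition_assessed,tristate,met|not_met,Assessment-of-malnutrition indicator; empty = missing
orthogeriatric_management,tristate,met|not_met,Orthogeriatric-management indicator; empty = missing
certified_surgeon,tristate,met|not_met,Operation by certified trauma surgeon; empty = missing
complication_any,tristate,yes|no,Any in-hospital complication; empty = missing
complication_types,list,semicolon-separated subtypes,"Optional subtypes: anaemia;delirium;pneumonia;urinary_tract_infection;in_hospital_fall;heart_failure;renal_insufficiency;pulmonary_embolism;wound_infection;pressure_ulcer"
in_hospital_death,tristate,yes|no,In-hospital death; empty = missing
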