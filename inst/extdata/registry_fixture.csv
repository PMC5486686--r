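patient_id,region,sex,age_years,admission_date,icd10_code,hip_surgery,neoplasia,refused_hospitalization,source
P001,vinnitsa_city,female,72,2011-03-14,S72.0,TRUE,FALSE,FALSE,hospital
P002,vinnitsa_city,male,68,2011-05-02,S72.1,TRUE,FALSE,FALSE,hospital
P003,uzhgorod,female,81,2011-03-04,S72.2,TRUE,FALSE,FALSE,hospital
P001,vinnitsa_city,female,72,2011-03-24,S72.0,TRUE,FALSE,FALSE,hospital
P004,uzhgorod,male,75,2011-06-11,S72.0,FALSE,TRUE,FALSE,hospital
P005,vinnitsa_area,female,79,2011-02-05,S72.9,FALSE,FALSE,FALSE,outpatient
P006,vinnitsa_area,male,70,2011-08-17,S72.9,TRUE,FALSE,FALSE,hospital
P007,uzhgorod,female,84,2011-11-29,S72.1,FALSE,FALSE,TRUE,ambulance
P003,uzhgorod,female,80,2010-08-16,S72.2,TRUE,FALSE,FALSE,hospital
P008,vinnitsa_city,male,66,2011-07-07,S73.0,FALSE,FALSE,FALSE,hospital
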