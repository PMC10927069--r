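group,metric,value
men,absenteeism_total_meur,305.2
men,sickness_total_meur,183.2
men,absenteeism_avg_eur,1903.0
men,sickness_avg_eur,1141.9
women,absenteeism_total_meur,868.5
women,sickness_total_meur,580.7
women,absenteeism_avg_eur,3909.0
women,sickness_avg_eur,2613.6
all,weighted_employees,1230754
all,national_fulltime_workforce_2022,2275785
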