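disease,study,population,information_source,origin,year,prevalence_pct
Autoimmune thyroiditis,this_study,741 adults,EHR,France,2015,12.6
Autoimmune thyroiditis,Cosnes,378 children / 546 adults,questionnaire,France,2008,6.0
Autoimmune thyroiditis,Iqbal,356 adults,questionnaire,Canada,2013,10.6
Autoimmune thyroiditis,Volta,770 adults,questionnaire,Italy,2012,26.3
Autoimmune thyroiditis,Collin,335 adults,hospital records,Finland,1994,7.5
Autoimmune thyroiditis,Stordal,3006 children,national register,Norway,2011,1.4
Autoimmune thyroiditis,Diamanti,558 children,serology,Italy,2011,12.0
Autoimmune thyroiditis,Van der Pals,335 children,serology,Sweden,2014,7.7
Autoimmune thyroiditis,Sategna-Guidetti,241 adults,serology,Italy,2001,30.2
Autoimmune thyroiditis,Counsell,107 adults,serology,Scotland,1994,15.0
Type 1 diabetes mellitus,this_study,741 adults,EHR,France,2015,2.3
Type 1 diabetes mellitus,Cosnes,378 children / 546 adults,questionnaire,France,2008,6.5
Type 1 diabetes mellitus,Iqbal,356 adults,questionnaire,Canada,2013,2.2
Type 1 diabetes mellitus,Stordal,3006 children,national register,Norway,2011,3.0
Type 1 diabetes mellitus,Diamanti,558 children,serology,Italy,2011,5.4
Type 1 diabetes mellitus,Van der Pals,335 children,serology,Sweden,2014,4.7
Dermatitis herpetiformis,this_study,741 adults,EHR,France,2015,2.0
Dermatitis herpetiformis,Cosnes,378 children / 546 adults,questionnaire,France,2008,3.1
Dermatitis herpetiformis,Iqbal,356 adults,questionnaire,Canada,2013,13.5
Dermatitis herpetiformis,Collin,335 adults,hospital records,Finland,1994,4.0
Rheumatoid disease,this_study,741 adults,EHR,France,2015,0.9
Rheumatoid disease,Cosnes,378 children / 546 adults,questionnaire,France,2008,0.7
Rheumatoid disease,Iqbal,356 adults,questionnaire,Canada,2013,4.5
Rheumatoid disease,Collin,335 adults,hospital records,Finland,1994,1.8
Autoimmune hepatitis,this_study,741 adults,EHR,France,2015,0.9
Autoimmune hepatitis,Cosnes,378 children / 546 adults,questionnaire,France,2008,1.2
Autoimmune hepatitis,Stordal,3006 children,national register,Norway,2011,0.0
Sjogren's syndrome,this_study,741 adults,EHR,France,2015,0.8
Sjogren's syndrome,Cosnes,378 children / 546 adults,questionnaire,France,2008,0.2
Sjogren's syndrome,Iqbal,356 adults,questionnaire,Canada,2013,0.8
Sjogren's syndrome,Collin,335 adults,hospital records,Finland,1994,3.3
Addison's disease,this_study,741 adults,EHR,France,2015,0.4
Addison's disease,Cosnes,378 children / 546 adults,questionnaire,France,2008,0.2
Addison's disease,Collin,335 adults,hospital records,Finland,1994,0.6
Systemic lupus,this_study,741 adults,EHR,France,2015,0.3
Systemic lupus,Cosnes,378 children / 546 adults,questionnaire,France,2008,0.2
Systemic lupus,Iqbal,356 adults,questionnaire,Canada,2013,1.1
Multiple sclerosis,this_study,741 adults,EHR,France,2015,0.1
Multiple sclerosis,Cosnes,378 children / 546 adults,questionnaire,France,2008,0.1
Antiphospholipid syndrome,this_study,741 adults,EHR,France,2015,0.0
Antiphospholipid syndrome,Cosnes,378 children / 546 adults,questionnaire,France,2008,0.2
Myasthenia gravis,this_study,741 adults,EHR,France,2015,0.0
Myasthenia gravis,Cosnes,378 children / 546 adults,questionnaire,France,2008,0.2
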