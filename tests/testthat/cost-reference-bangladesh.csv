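approach,sex,age_group,people,aspirin,enalapril,hydrochlorothiazide,simvastatin,total
total_risk,male,40-49,4000,6570.0,34748.0,12118.0,62196.0,115632.0
total_risk,male,50-59,1000,1642.5,8687.0,3029.5,15549.0,28908.0
total_risk,male,60-69,15000,24637.5,130305.0,45442.5,233235.0,433620.0
total_risk,male,ge70,70000,114975.0,608090.0,212065.0,1088430.0,2023560.0
total_risk,male,all,10000,16425.0,86870.0,30295.0,155490.0,289080.0
total_risk,female,40-49,0,0.0,0.0,0.0,0.0,0.0
total_risk,female,50-59,0,0.0,0.0,0.0,0.0,0.0
total_risk,female,60-69,0,0.0,0.0,0.0,0.0,0.0
total_risk,female,ge70,16000,26280.0,138992.0,48472.0,248784.0,462528.0
total_risk,female,all,1000,1642.5,8687.0,3029.5,15549.0,28908.0
total_risk,all,40-49,2000,3285.0,17374.0,6059.0,31098.0,57816.0
total_risk,all,50-59,1000,1642.5,8687.0,3029.5,15549.0,28908.0
total_risk,all,60-69,7000,11497.5,60809.0,21206.5,108843.0,202356.0
total_risk,all,ge70,43000,70627.5,373541.0,130268.5,668607.0,1243044.0
total_risk,all,all,5000,8212.5,43435.0,15147.5,77745.0,144540.0
single_risk,male,40-49,171000,280867.5,1485477.0,518044.5,2658879.0,4943268.0
single_risk,male,50-59,217000,356422.5,1885079.0,657401.5,3374133.0,6273036.0
single_risk,male,60-69,305000,500962.5,2649535.0,923997.5,4742445.0,8816940.0
single_risk,male,ge70,294000,482895.0,2553978.0,890673.0,4571406.0,8498952.0
single_risk,male,all,221000,362992.5,1919827.0,669519.5,3436329.0,6388668.0
single_risk,female,40-49,225000,369562.5,1954575.0,681637.5,3498525.0,6504300.0
single_risk,female,50-59,306000,502605.0,2658222.0,927027.0,4757994.0,8845848.0
single_risk,female,60-69,287000,471397.5,2493169.0,869466.5,4462563.0,8296596.0
single_risk,female,ge70,337000,553522.5,2927519.0,1020941.5,5240013.0,9741996.0
single_risk,female,all,267000,438547.5,2319429.0,808876.5,4151583.0,7718436.0
single_risk,all,40-49,202000,331785.0,1754774.0,611959.0,3140898.0,5839416.0
single_risk,all,50-59,263000,431977.5,2284681.0,796758.5,4089387.0,7602804.0
single_risk,all,60-69,295000,484537.5,2562665.0,893702.5,4586955.0,8527860.0
single_risk,all,ge70,316000,519030.0,2745092.0,957322.0,4913484.0,9134928.0
single_risk,all,all,246000,404055.0,2137002.0,745257.0,3825054.0,7111368.0
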