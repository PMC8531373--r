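"specimen_id","site","sex","M1","M5","M8","M9","M10","M12","M17","M29","M30","M31","M40","M43","M45","M46","M48","M51","M52","M54","M55"
"Yahuai","Yahuai","F","190","92","147","109","130","114","143","120","119","110","94","115","152","98","62","(41)","35","25","48"
"04HCH3-M18","Hang Cho","F","192","103","138","100","112","115","135","130","119","91","97","113","128","95","61","42","31","26","47"
"4MDD-M11","Mai Da Dieu","F","181","89","126","89","100","116","(130)","108","111","103","","112","120","103","58","38","33","27","43"
"4BD1-M4","Bau Du","F","172","90","133","93","110","101","133","110","107","","","108","(134)","110","59","41","31","26","44"
"No. 5","Xiaoma","F","162","","128","87","102","","(132)","98","","","","96","(138)","(104)","59","38","31","26","43"
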