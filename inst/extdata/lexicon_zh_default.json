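{
  "id": "zh_default",
  "disease_terms": {
    "精神分裂症": "F20",
    "抑郁症": "F32",
    "重性抑郁障碍": "F32",
    "抑郁发作": "F32",
    "双相情感障碍": "F31",
    "躁郁症": "F31",
    "其他非器质性精神障碍": "F28",
    "未特定的非器质性精神病": "F29"
  },
  "kinship_terms": {
    "父亲": {"relation": "father", "degree": "first"},
    "母亲": {"relation": "mother", "degree": "first"},
    "哥哥": {"relation": "elder_brother", "degree": "first"},
    "姐姐": {"relation": "elder_sister", "degree": "first"},
    "弟弟": {"relation": "younger_brother", "degree": "first"},
    "妹妹": {"relation": "younger_sister", "degree": "first"},
    "儿子": {"relation": "son", "degree": "first"},
    "女儿": {"relation": "daughter", "degree": "first"},
    "祖父": {"relation": "grandfather", "degree": "second"},
    "祖母": {"relation": "grandmother", "degree": "second"},
    "外祖父": {"relation": "maternal_grandfather", "degree": "second"},
    "外祖母": {"relation": "maternal_grandmother", "degree": "second"},
    "叔叔": {"relation": "uncle", "degree": "second"},
    "姑姑": {"relation": "paternal_aunt", "degree": "second"},
    "舅舅": {"relation": "maternal_uncle", "degree": "second"},
    "姨母": {"relation": "maternal_aunt", "degree": "second"},
    "侄子": {"relation": "nephew", "degree": "second"},
    "侄女": {"relation": "niece", "degree": "second"},
    "表哥": {"relation": "cousin", "degree": "third"},
    "表姐": {"relation": "cousin", "degree": "third"},
    "表弟": {"relation": "cousin", "degree": "third"},
    "表妹": {"relation": "cousin", "degree": "third"},
    "堂哥": {"relation": "cousin", "degree": "third"},
    "堂姐": {"relation": "cousin", "degree": "third"},
    "曾祖父": {"relation": "great_grandfather", "degree": "third"},
    "曾祖母": {"relation": "great_grandmother", "degree": "third"}
  },
  "negation_cues": ["否认", "没有", "未发现", "无明显"],
  "section_cues": ["家族史"],
  "templates": {
    "fh_intro": "家族史：",
    "fh_event": "{kin}患有{disease}",
    "event_sep": "，",
    "sentence_end": "。",
    "denial_body": "否认两系三代精神疾病家族史",
    "distractor": "既往曾被怀疑为{disease}。",
    "fillers": [
      "患者本次因情绪低落一月入院。",
      "入院时神志清楚，对答切题。",
      "病程中渐起兴趣减退，伴乏力。",
      "平素性格内向，人际关系尚可。",
      "既往体健，否认重大躯体疾病史。",
      "饮食睡眠欠佳，二便正常。",
      "查体：心肺腹未查及异常，神经系统检查阴性。",
      "近期体重较前下降，自觉精力不足。"
    ],
    "padding": "余病史同前，此次入院后完善相关检查，继续观察病情变化，必要时调整治疗方案。",
    "wordlist": ["入院", "情绪低落", "神志清楚", "兴趣减退", "体重", "睡眠",
                 "患有", "查体", "既往", "治疗", "检查", "病程", "症状"]
  }
}
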